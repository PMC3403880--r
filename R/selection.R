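#' Cloud display specification
#'
#' Bundles the selection and scaling configuration: how many substructures
#' to display, how log-frequency maps to image magnification, which
#' ubiquitous structures to suppress, and the color scheme.
#'
#' The useful display set is 100-250 substructures (roughly 30-50 of them
#' large enough to be recognized at a glance); `top_n = 200` is the default.
#' Benzene is the default stop-structure: it is by far the most frequent
#' scaffold in any large collection and carries no information, exactly
#' like a stop word in a text cloud.
#'
#' @param top_n number of substructures to display.
#' @param min_scale,max_scale magnification assigned to the rarest and the
#'   most frequent displayed substructure; linear interpolation in
#'   log-frequency in between. Scales multiply linear image dimensions.
#' @param stop_structures SMILES of structures never displayed (matched by
#'   canonical SMILES equality, not substructure).
#' @param drop_singletons drop frequency-1 records before top-N selection.
#' @param color_scheme `"none"`, `"activity_intensity"` or `"target_class"`.
#' @return an object of class `cloud_spec`.
#' @export
cloud_spec <- function(top_n = 200L, min_scale = 1.0, max_scale = 3.5,
                       stop_structures = "c1ccccc1",
                       drop_singletons = FALSE,
                       color_scheme = c("none", "activity_intensity",
                                        "target_class")) {
  color_scheme <- match.arg(color_scheme)
  stopifnot(top_n >= 1L, min_scale > 0, max_scale > 0,
            min_scale < max_scale, is.logical(drop_singletons))
  structure(list(top_n = as.integer(top_n), min_scale = min_scale,
                 max_scale = max_scale,
                 stop_structures = stop_structures,
                 drop_singletons = drop_singletons,
                 color_scheme = color_scheme),
            class = "cloud_spec")
}

#' Select the display set from aggregated records
#'
#' Removes stop-structures, optionally singletons, sorts by frequency
#' (descending; ties broken by canonical SMILES, ascending, C locale) and
#' keeps the first `top_n` records.
#'
#' @param records aggregated records ([reduce_collection()] output or the
#'   same columns).
#' @param spec a [cloud_spec()].
#' @return the selected records, with attribute `"selection_report"` giving
#'   `stop_removed`, `singleton_removed` and `below_top_n` counts.
#' @export
select_top <- function(records, spec = cloud_spec()) {
  stopifnot(is.data.frame(records),
            all(c("canonical_smiles", "frequency") %in% names(records)))
  stopifnot(!anyDuplicated(records$canonical_smiles))
  stop_can <- canonicalize_smiles(spec$stop_structures)
  is_stop <- records$canonical_smiles %in% stop_can
  out <- records[!is_stop, , drop = FALSE]
  singleton_removed <- 0L
  if (isTRUE(spec$drop_singletons)) {
    singleton_removed <- sum(out$frequency == 1L)
    out <- out[out$frequency > 1L, , drop = FALSE]
  }
  if (nrow(out) == 0L)
    stop("no displayable records: all records are stop-structures",
         if (spec$drop_singletons) " or singletons")
  out <- out[order(-out$frequency, out$canonical_smiles,
                   method = "radix"), , drop = FALSE]
  below <- max(0L, nrow(out) - spec$top_n)
  out <- utils::head(out, spec$top_n)
  rownames(out) <- NULL
  attr(out, "selection_report") <- list(
    stop_removed = sum(is_stop),
    singleton_removed = singleton_removed,
    below_top_n = below
  )
  out
}

#' Log-frequency image magnification
#'
#' Scaffold frequencies follow a long-tail distribution, so raw counts are
#' useless as direct size factors; sizes are interpolated linearly in
#' log-frequency instead:
#' `min_scale + (max_scale - min_scale) * (log f - log f_min) /
#' (log f_max - log f_min)`.
#' When all displayed frequencies are equal the midpoint of the scale range
#' is used.
#'
#' @param frequency integer vector of frequencies in `[f_min, f_max]`.
#' @param f_min,f_max frequency range of the display set (both >= 1).
#' @param spec a [cloud_spec()] supplying `min_scale` / `max_scale`.
#' @return numeric vector of magnifications.
#' @export
scale_factor <- function(frequency, f_min, f_max, spec = cloud_spec()) {
  stopifnot(f_min >= 1, f_max >= f_min)
  if (any(frequency < f_min | frequency > f_max))
    stop("frequency outside [f_min, f_max]")
  if (f_min == f_max)
    return(rep((spec$min_scale + spec$max_scale) / 2, length(frequency)))
  spec$min_scale + (spec$max_scale - spec$min_scale) *
    (log(frequency) - log(f_min)) / (log(f_max) - log(f_min))
}

#' Read a SMILES file
#'
#' One molecule per line, `SMILES[<tab>NAME]`; lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path file path.
#' @return `data.frame` with columns `smiles`, `name` (`NA` when absent).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1L),
    name = vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_,
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a pre-aggregated substructure table
#'
#' Delimited file with a header row. Recognized columns (case-insensitive):
#' `smiles` (required), `count` (default 1), `active` (0/1 per row) or
#' `activity_ratio` (in \[0,1\]), `target_class`. SMILES are canonicalized
#' and duplicate keys aggregated.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return aggregated records as from [reduce_collection()].
#' @export
read_substructure_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!"smiles" %in% names(df)) stop("table must have a 'smiles' column")
  count <- if ("count" %in% names(df)) as.integer(df$count)
           else rep(1L, nrow(df))
  stopifnot(all(count >= 1L))
  can <- canonicalize_smiles(df$smiles)
  failed <- sum(is.na(can))
  ok <- !is.na(can)
  key <- can[ok]; count <- count[ok]
  freq <- tapply(count, key, sum)
  rec <- data.frame(canonical_smiles = names(freq), kind = NA_character_,
                    frequency = as.integer(freq), stringsAsFactors = FALSE)
  has_ring <- function(s) {
    m <- mc_parse_smiles(s)
    !is.null(m) && length(mc_ring_atoms(mc_graph(m))) > 0L
  }
  rec$kind <- ifelse(grepl("*", rec$canonical_smiles, fixed = TRUE),
                     "substituent",
                     ifelse(vapply(rec$canonical_smiles, has_ring, logical(1)),
                            "scaffold", "chain"))
  if ("activity_ratio" %in% names(df)) {
    wr <- tapply(df$activity_ratio[ok] * count, key, sum)
    rec$activity_ratio <- as.numeric(wr[rec$canonical_smiles]) / rec$frequency
  } else if ("active" %in% names(df)) {
    na_ <- tapply(as.integer(df$active[ok]) * count, key, sum)
    rec$activity_ratio <- as.numeric(na_[rec$canonical_smiles]) / rec$frequency
  }
  if ("target_class" %in% names(df)) {
    cls <- as.character(df$target_class[ok])
    for (lab in sort(unique(cls[!is.na(cls) & nzchar(cls)]), method = "radix")) {
      cnt <- tapply((!is.na(cls) & cls == lab) * count, key, sum)
      rec[[paste0("class_", lab)]] <-
        as.numeric(cnt[rec$canonical_smiles]) / rec$frequency
    }
  }
  rec <- rec[order(-rec$frequency, rec$canonical_smiles,
                   method = "radix"), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "report") <- list(parsed = sum(ok), failed = failed)
  rec
}

#' Write the selected, scaled display table
#'
#' The exchange format between pipeline stages: tab-separated
#' `canonical_smiles, frequency, scale` plus any annotation columns.
#'
#' @param records selected records with a `scale` column.
#' @param path output path.
#' @export
write_display_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
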