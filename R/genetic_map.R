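#' Build a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `marker`, `chrom`, `pos_bp` (physical position, base pairs) and `pos_cM`
#' (genetic position, centimorgan). Positions must be strictly increasing
#' within a chromosome and marker ids unique.
#'
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param spacing_cM genetic distance between adjacent markers (cM).
#' @param bp_per_cM physical bp per cM used to lay out `pos_bp`
#'   (yeast averages roughly 2-3 kb/cM).
#' @return a validated genetic map data frame.
#' @export
#' @examples
#' map <- make_genetic_map(n_chrom = 2, markers_per_chrom = 5)
make_genetic_map <- function(n_chrom = 5, markers_per_chrom = 12,
                             spacing_cM = 10, bp_per_cM = 2000) {
  stopifnot(n_chrom >= 1, markers_per_chrom >= 1, spacing_cM >= 0)
  cM <- (seq_len(markers_per_chrom) - 1) * spacing_cM
  map <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    data.frame(
      marker = sprintf("c%02d_m%02d", ch, seq_len(markers_per_chrom)),
      chrom = sprintf("chr%02d", ch),
      pos_bp = as.integer(round(cM * bp_per_cM)) + 1000L,
      pos_cM = cM,
      stringsAsFactors = FALSE
    )
  }))
  rownames(map) <- NULL
  validate_genetic_map(map)
  map
}

#' Validate a genetic map
#'
#' Checks the genetic-map invariants: required columns, unique marker ids,
#' non-negative cM and strictly increasing positions within each chromosome.
#'
#' @param map a genetic map data frame.
#' @return the map, invisibly; stops on violation.
#' @export
validate_genetic_map <- function(map) {
  required <- c("marker", "chrom", "pos_bp", "pos_cM")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0L) {
    stop("genetic map is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(map) == 0L) stop("genetic map is empty")
  if (anyDuplicated(map$marker)) {
    stop("duplicate marker ids in map: ",
         paste(unique(map$marker[duplicated(map$marker)]), collapse = ", "))
  }
  if (any(map$pos_cM < 0)) stop("negative cM positions in map")
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    if (is.unsorted(sub$pos_bp, strictly = TRUE)) {
      stop("physical positions not strictly increasing on ", ch)
    }
    if (is.unsorted(sub$pos_cM)) {
      stop("genetic positions not non-decreasing on ", ch)
    }
  }
  invisible(map)
}
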