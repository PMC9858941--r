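#' Genotype matrix with marker map
#'
#' Container for an animals-by-markers allele-dosage matrix (0/1/2 copies of
#' the counted allele, `NA` for missing calls, fractional values allowed after
#' mean imputation) together with its marker map.
#'
#' @param dosages numeric matrix, animals in rows and markers in columns.
#'   Row names are taken as animal identifiers and column names as marker
#'   identifiers; both must be present and unique. Values must lie in
#'   \[0, 2\] or be `NA`.
#' @param map data.frame with columns `marker_id`, `chrom` (chromosome label,
#'   coerced to character; sex chromosomes are usually labelled `"X"`/`"Y"`)
#'   and `pos` (1-based physical position). Must cover exactly the markers in
#'   `dosages`, in the same order.
#' @return an object of class `geno_matrix`: a list with elements `dosages`
#'   and `map`.
#' @seealso [simulate_genotypes()], [filter_markers()], [impute_missing()]
#' @export
geno_matrix <- function(dosages, map) {
  if (!is.matrix(dosages) || !is.numeric(dosages)) {
    stop("`dosages` must be a numeric matrix", call. = FALSE)
  }
  an <- rownames(dosages)
  mk <- colnames(dosages)
  if (is.null(an) || anyDuplicated(an)) {
    stop("`dosages` needs unique row names (animal ids)", call. = FALSE)
  }
  if (is.null(mk) || anyDuplicated(mk)) {
    stop("`dosages` needs unique column names (marker ids)", call. = FALSE)
  }
  rng <- suppressWarnings(range(dosages, na.rm = TRUE)) # all-NA gives +/-Inf
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2] (copies of the counted allele)",
         call. = FALSE)
  }
  if (!is.data.frame(map) ||
      !all(c("marker_id", "chrom", "pos") %in% names(map))) {
    stop("`map` must have columns marker_id, chrom, pos", call. = FALSE)
  }
  if (nrow(map) != ncol(dosages) ||
      !identical(as.character(map$marker_id), mk)) {
    stop("`map` must list exactly the markers of `dosages`, in order",
         call. = FALSE)
  }
  if (any(map$pos < 1, na.rm = TRUE)) {
    stop("marker positions must be 1-based (>= 1)", call. = FALSE)
  }
  map <- data.frame(
    marker_id = as.character(map$marker_id),
    chrom = as.character(map$chrom),
    pos = as.numeric(map$pos),
    stringsAsFactors = FALSE
  )
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_mis <- sum(is.na(x$dosages))
  cat(sprintf(
    "geno_matrix: %d animals x %d markers on %d chromosome(s), %d missing call(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)), n_mis
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

n_animals <- function(g) nrow(g$dosages)
n_markers <- function(g) ncol(g$dosages)

stopifnot_geno <- function(g) {
  if (!inherits(g, "geno_matrix")) {
    stop("expected a `geno_matrix` (see ?geno_matrix)", call. = FALSE)
  }
  invisible(g)
}

# subset a geno_matrix, keeping dosages and map in register
subset_geno <- function(g, animals = NULL, markers = NULL) {
  d <- g$dosages
  map <- g$map
  if (!is.null(animals)) d <- d[animals, , drop = FALSE]
  if (!is.null(markers)) {
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  geno_matrix(d, map)
}
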