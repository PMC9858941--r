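#' Read and write genotype, phenotype and result files
#'
#' Plain-text interchange formats used throughout the package:
#' * dosage TSV: header row of marker ids, first column `animal_id`, one
#'   dosage per cell (`NA` for missing), plus a separate 3-column map TSV
#'   (`marker_id`, `chrom`, `pos`);
#' * PLINK `.ped`/`.map` pair (alleles `A`/`B`, `0` for missing, counted
#'   allele `A`);
#' * phenotype CSV with columns `animal_id`, `trait`, `env`, `value`;
#' * GRM as TSV with animal ids plus a JSON sidecar holding the scale and
#'   blending constant;
#' * gene intervals as BED (0-based half-open, converted to 1-based
#'   inclusive) or 4-column TSV (`gene`, `chrom`, `start`, `end`).
#'
#' @name gxeblup-io
NULL

#' @rdname gxeblup-io
#' @param g a [geno_matrix()].
#' @param dosage_file path of the dosage TSV.
#' @param map_file path of the marker-map TSV; optional on read (a
#'   single-chromosome map with unit stride is synthesized, with a warning).
#' @return `write_dosages()` returns the paths invisibly; `read_dosages()`
#'   a [geno_matrix()].
#' @export
write_dosages <- function(g, dosage_file, map_file = NULL) {
  stopifnot_geno(g)
  df <- data.frame(animal_id = rownames(g$dosages), g$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, dosage_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_file)) {
    write.table(g$map, map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(dosage_file, map_file))
}

#' @rdname gxeblup-io
#' @export
read_dosages <- function(dosage_file, map_file = NULL) {
  df <- read.table(dosage_file, header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  mode(d) <- "numeric"
  rownames(d) <- as.character(df[[1]])
  if (!is.null(map_file)) {
    map <- read.table(map_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "numeric"))
  } else {
    warning("no map file given; assuming one chromosome, unit marker stride",
            call. = FALSE)
    map <- data.frame(marker_id = colnames(d), chrom = "1",
                      pos = seq_len(ncol(d)), stringsAsFactors = FALSE)
  }
  geno_matrix(d, map)
}

#' @rdname gxeblup-io
#' @param prefix path prefix for the PLINK pair (`<prefix>.ped`,
#'   `<prefix>.map`).
#' @export
write_plink <- function(g, prefix) {
  stopifnot_geno(g)
  d <- g$dosages
  if (any(!is.na(d) & d != round(d))) {
    stop("PLINK output needs integer dosages (write before imputation)",
         call. = FALSE)
  }
  allele_str <- c(`0` = "B B", `1` = "A B", `2` = "A A")
  ped_geno <- apply(d, 1, function(row) {
    s <- ifelse(is.na(row), "0 0", allele_str[as.character(row)])
    paste(s, collapse = " ")
  })
  ped <- paste(rownames(d), rownames(d), 0, 0, 0, -9, ped_geno)
  writeLines(ped, paste0(prefix, ".ped"))
  map <- data.frame(g$map$chrom, g$map$marker_id, 0, g$map$pos)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname gxeblup-io
#' @export
read_plink <- function(prefix) {
  map_raw <- read.table(paste0(prefix, ".map"), header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  map <- data.frame(marker_id = map_raw[[2]], chrom = map_raw[[1]],
                    pos = map_raw[[4]], stringsAsFactors = FALSE)
  lines <- readLines(paste0(prefix, ".ped"))
  fields <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  d <- matrix(NA_real_, length(fields), m)
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6 + 2 * m) {
      stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, got ", length(f), call. = FALSE)
    }
    ids[i] <- f[2]
    a1 <- f[seq(7, length(f), by = 2)]
    a2 <- f[seq(8, length(f), by = 2)]
    miss <- a1 == "0" | a2 == "0"
    d[i, ] <- ifelse(miss, NA_real_, (a1 == "A") + (a2 == "A"))
  }
  rownames(d) <- ids
  colnames(d) <- map$marker_id
  geno_matrix(d, map)
}

#' @rdname gxeblup-io
#' @param y phenotype data.frame (`animal_id`, `trait`, `env`, `value`).
#' @param file output/input path.
#' @export
write_phenotypes <- function(y, file) {
  cols <- intersect(c("animal_id", "trait", "env", "value"), names(y))
  if (!all(c("animal_id", "env", "value") %in% cols)) {
    stop("phenotypes need columns animal_id, env, value", call. = FALSE)
  }
  write.table(y[, cols], file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname gxeblup-io
#' @export
read_phenotypes <- function(file) {
  read.table(file, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' @rdname gxeblup-io
#' @param effects a `snp_effect_table`.
#' @export
write_snp_effects <- function(effects, file) {
  if (!inherits(effects, "snp_effect_table")) {
    stop("`effects` must come from backsolve_snp_effects()", call. = FALSE)
  }
  write.table(as.data.frame(effects), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname gxeblup-io
#' @param grm a [vanraden_g()] object.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot_grm(grm)
  df <- data.frame(animal_id = grm$animal_ids, grm$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("animal_id", grm$animal_ids)
  write.table(df, paste0(prefix, ".grm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(scale = grm$scale, blend_epsilon = grm$epsilon,
         n_animals = length(grm$animal_ids)),
    paste0(prefix, ".grm.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname gxeblup-io
#' @export
read_grm <- function(prefix) {
  df <- read.table(paste0(prefix, ".grm.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  meta <- jsonlite::read_json(paste0(prefix, ".grm.json"), simplifyVector = TRUE)
  structure(list(mat = mat, scale = meta$scale,
                 epsilon = meta$blend_epsilon,
                 animal_ids = df[[1]]), class = "grm")
}

#' @rdname gxeblup-io
#' @param report a `qc_report`.
#' @export
write_qc_report <- function(report, file) {
  if (!inherits(report, "qc_report")) stop("expected a qc_report", call. = FALSE)
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname gxeblup-io
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @export
read_gene_intervals <- function(file, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    df <- read.table(file, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED needs chrom, start, end, name", call. = FALSE)
    out <- data.frame(
      gene = as.character(df[[4]]),
      chrom = sub("^chr", "", as.character(df[[1]])),
      start = as.numeric(df[[2]]) + 1,  # 0-based half-open -> 1-based inclusive
      end = as.numeric(df[[3]]),
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.table(file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "start", "end")
    if (!all(need %in% names(df))) {
      stop("TSV gene file needs columns gene, chrom, start, end", call. = FALSE)
    }
    out <- data.frame(
      gene = as.character(df$gene), chrom = as.character(df$chrom),
      start = as.numeric(df$start), end = as.numeric(df$end),
      stringsAsFactors = FALSE
    )
  }
  if (any(out$start > out$end) || any(out$start < 1)) {
    stop("gene intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  out
}
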