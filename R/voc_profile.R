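#' @title VOC abundance profiles
#' @description Functions for parsing, filtering and summarizing headspace
#'   GC-MS volatile-compound tables: per-sample percent abundances for a set
#'   of identified compounds, grouped into monoterpenes, sesquiterpenes and
#'   other chemical classes.
#' @name voc_profile
NULL

VOC_CLASSES <- c("MONOTERPENE", "SESQUITERPENE", "OTHER")

#' Filter chromatographic peaks on identification and detection quality
#'
#' Keeps peaks whose spectral-library match quality (relative standard
#' intensity, RSI) and chromatographic signal-to-noise ratio both exceed
#' their thresholds. Both comparisons are strict: a peak exactly at a
#' threshold is dropped.
#'
#' @param peaks data.frame with numeric columns `rsi` and `snr` (S/N in
#'   decibels); other columns (retention time, annotation) pass through.
#' @param rsi_min minimum RSI, exclusive. Default 600.
#' @param snr_min minimum S/N (dB), exclusive. Default 50.
#' @return the subset of `peaks` with `rsi > rsi_min & snr > snr_min`,
#'   input order preserved.
#' @examples
#' pk <- data.frame(rsi = c(601, 600, 900), snr = c(51, 90, 50))
#' filter_peaks(pk)  # keeps only the first row
#' @export
filter_peaks <- function(peaks, rsi_min = 600, snr_min = 50) {
  stopifnot(is.data.frame(peaks), is.finite(rsi_min), is.finite(snr_min))
  if (nrow(peaks) == 0L) return(peaks)
  for (col in c("rsi", "snr")) {
    if (!col %in% names(peaks))
      stop("peak table lacks column '", col, "'")
    if (!is.numeric(peaks[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(peaks[[col]]))))
      stop("non-numeric '", col, "' in peak row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (anyNA(peaks$rsi) || anyNA(peaks$snr) ||
      any(!is.finite(peaks$snr)) || any(peaks$rsi < 0))
    stop("rsi must be >= 0 and snr finite for every peak")
  peaks[peaks$rsi > rsi_min & peaks$snr > snr_min, , drop = FALSE]
}

.normalize_abundance_cell <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("ND", "nd", "", "-", "NA")] <- NA_character_
  x <- sub("%$", "", x)
  x <- gsub(",", ".", x, fixed = TRUE)
  bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad))
    stop("unparseable abundance cell(s): ",
         paste(unique(x[bad]), collapse = ", "))
  as.numeric(x)
}

#' Parse a VOC compound abundance table
#'
#' Reads a delimited text table (comma or tab separated) with columns
#' `compound_id, name, cas, formula, class` followed by one column per
#' sampled tree. Abundance cells may carry a `%` suffix or use a decimal
#' comma; `ND`, `-` and empty cells mean not detected and become `NA`.
#'
#' @param path path to the delimited file.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a `voc_profile` object: a list with `samples` (character vector
#'   of sample ids in column order) and `compounds` (data.frame with one row
#'   per compound and numeric abundance columns).
#' @details Each compound must be detected in at least one sample and all
#'   present abundances must lie in \[0, 100\]; the chemical class must be
#'   one of `MONOTERPENE`, `SESQUITERPENE`, `OTHER`. Abundance columns are
#'   used exactly as printed; they are not renormalized to sum to 100.
#' @seealso [write_compound_table()] for the inverse operation,
#'   [aroeira_profile()] for the packaged worked-example table.
#' @export
parse_compound_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", encoding = "UTF-8",
                           comment.char = "")
  fixed <- c("compound_id", "name", "cas", "formula", "class")
  if (!all(fixed %in% names(raw)))
    stop("compound table must have columns: ",
         paste(fixed, collapse = ", "), " plus one column per sample")
  samples <- setdiff(names(raw), fixed)
  if (length(samples) == 0L) stop("no sample columns found")
  if (anyDuplicated(samples)) stop("duplicated sample ids")

  cls <- toupper(trimws(raw$class))
  cls[cls %in% c("MONOTERPENES")] <- "MONOTERPENE"
  cls[cls %in% c("SESQUITERPENES")] <- "SESQUITERPENE"
  cls[cls %in% c("OTHER CLASSES", "OTHERS")] <- "OTHER"
  unknown <- setdiff(unique(cls), VOC_CLASSES)
  if (length(unknown))
    stop("unknown chemical class label(s): ", paste(unknown, collapse = ", "))

  compounds <- data.frame(
    compound_id = as.integer(raw$compound_id),
    name = trimws(raw$name), cas = trimws(raw$cas),
    formula = trimws(raw$formula), class = cls,
    stringsAsFactors = FALSE
  )
  if (anyNA(compounds$compound_id) || anyDuplicated(compounds$compound_id))
    stop("compound_id must be unique integers")
  for (s in samples) compounds[[s]] <- .normalize_abundance_cell(raw[[s]])

  ab <- as.matrix(compounds[samples])
  out_of_range <- which(!is.na(ab) & (ab < 0 | ab > 100), arr.ind = TRUE)
  if (nrow(out_of_range))
    stop("abundance outside [0,100] for compound ",
         compounds$name[out_of_range[1, 1]])
  all_nd <- rowSums(!is.na(ab)) == 0L
  if (any(all_nd))
    stop("compound(s) not detected in any sample: ",
         paste(compounds$name[all_nd], collapse = ", "))

  structure(list(samples = samples, compounds = compounds),
            class = "voc_profile")
}

#' Write a VOC profile back to delimited text
#'
#' Canonical serialization: decimal points, no `%` suffix, `ND` for missing
#' cells. `parse_compound_table()` on the result reproduces the profile.
#'
#' @param profile a `voc_profile`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(profile, path, sep = ",") {
  stopifnot(inherits(profile, "voc_profile"))
  out <- profile$compounds
  for (s in profile$samples) {
    v <- out[[s]]
    out[[s]] <- ifelse(is.na(v), "ND", format(v, trim = TRUE, digits = 15))
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.voc_profile <- function(x, ...) {
  cat("VOC profile:", nrow(x$compounds), "compounds x",
      length(x$samples), "samples (", paste(x$samples, collapse = ", "),
      ")\n")
  cc <- class_counts(x)
  cat("  classes:", paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Load the packaged aroeira seed VOC table
#'
#' The worked-example dataset shipped with the package: 23 volatile
#' compounds identified by HS-SPME/GC-MS in seeds of five aroeira
#' (*Myracrodruon urundeuva*) trees, with percent abundances per tree.
#'
#' @return a `voc_profile` with samples `A.1` to `A.5`.
#' @examples
#' prof <- aroeira_profile()
#' class_counts(prof)
#' @export
aroeira_profile <- function() {
  parse_compound_table(
    system.file("extdata", "aroeira_seed_vocs.csv", package = "vocscreen",
                mustWork = TRUE))
}

#' Rank compounds of one sample by abundance
#'
#' @param profile a `voc_profile`.
#' @param sample_id one of `profile$samples`.
#' @return data.frame `(rank, compound_id, name, class, abundance)` of the
#'   compounds detected in the sample, sorted by descending abundance; ties
#'   broken by ascending `compound_id`.
#' @examples
#' summarize_sample(aroeira_profile(), "A.5")[1, ]  # 3-Carene, 55.2
#' @export
summarize_sample <- function(profile, sample_id) {
  stopifnot(inherits(profile, "voc_profile"))
  if (!sample_id %in% profile$samples)
    stop("unknown sample id: ", sample_id)
  cmp <- profile$compounds
  ab <- cmp[[sample_id]]
  keep <- !is.na(ab)
  ord <- order(-ab[keep], cmp$compound_id[keep])
  res <- data.frame(
    rank = seq_len(sum(keep)),
    compound_id = cmp$compound_id[keep][ord],
    name = cmp$name[keep][ord],
    class = cmp$class[keep][ord],
    abundance = ab[keep][ord],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' Count compounds per chemical class
#'
#' @param profile a `voc_profile`.
#' @return named integer vector over `MONOTERPENE`, `SESQUITERPENE`,
#'   `OTHER`; entries sum to the number of compounds.
#' @export
class_counts <- function(profile) {
  stopifnot(inherits(profile, "voc_profile"))
  cnt <- table(factor(profile$compounds$class, levels = VOC_CLASSES))
  setNames(as.integer(cnt), VOC_CLASSES)
}

#' In how many samples is a compound detected?
#'
#' @param profile a `voc_profile`.
#' @param compound a compound_id (integer) or exact compound name.
#' @return integer count of samples with a present (non-ND) abundance.
#' @examples
#' presence_across_samples(aroeira_profile(), "3-Carene")  # 5
#' @export
presence_across_samples <- function(profile, compound) {
  stopifnot(inherits(profile, "voc_profile"))
  cmp <- profile$compounds
  idx <- if (is.numeric(compound)) {
    which(cmp$compound_id == compound)
  } else {
    which(cmp$name == compound)
  }
  if (length(idx) != 1L) stop("unknown compound: ", compound)
  sum(!is.na(as.numeric(cmp[idx, profile$samples])))
}

#' Mean across-sample abundance per compound
#'
#' Not-detected cells count as zero, so the result is the compound's share
#' of the pooled molar content across all samples.
#'
#' @param profile a `voc_profile`.
#' @return named numeric vector (names = compound names), percent units.
#' @export
mean_abundance <- function(profile) {
  stopifnot(inherits(profile, "voc_profile"))
  ab <- as.matrix(profile$compounds[profile$samples])
  ab[is.na(ab)] <- 0
  setNames(rowMeans(ab), profile$compounds$name)
}
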