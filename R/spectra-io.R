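# Reading and writing spectra (MGF, optionally mzML), ground-truth tables
# and sequencing-result tables.

#' Construct a spectrum object
#'
#' A minimal container for one MS/MS spectrum: a peak list sorted by m/z,
#' the precursor m/z and charge, and optional collision energy / retention
#' time metadata. Peaks are stored as-is; all normalization happens at
#' encoding time.
#'
#' @param id Spectrum identifier (scalar character).
#' @param mz,intensity Numeric peak vectors of equal length.
#' @param precursor_mz Precursor m/z (> 0).
#' @param charge Integer precursor charge, 1..8.
#' @param collision_energy Optional normalized collision energy (NA if unknown).
#' @param retention_time Optional retention time in seconds (NA if unknown).
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(id, mz, intensity, precursor_mz, charge,
                     collision_energy = NA_real_, retention_time = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (precursor_mz <= 0) stop("precursor m/z must be positive")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
  }
  structure(
    list(
      id = as.character(id),
      mz = as.numeric(mz),
      intensity = as.numeric(intensity),
      precursor_mz = as.numeric(precursor_mz),
      charge = as.integer(charge),
      collision_energy = as.numeric(collision_energy),
      retention_time = as.numeric(retention_time)
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum %s: %d peaks, precursor %.4f Th, charge %d+>\n",
    x$id, length(x$mz), x$precursor_mz, x$charge
  ))
  invisible(x)
}

#' Read spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE and
#' RTINSECONDS headers. Records missing PEPMASS or CHARGE, or with a charge
#' outside 1..8, are skipped; the number of skipped records is reported as a
#' warning and attached as an attribute.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum()] objects, in file order, with attribute
#'   `"skipped"` giving the number of records dropped.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS at ", path)
  }
  skipped <- 0L
  out <- vector("list", length(begin))
  kept <- 0L
  for (k in seq_along(begin)) {
    block <- lines[(begin[k] + 1L):(end[k] - 1L)]
    hdr_idx <- grepl("=", block, fixed = TRUE)
    hdr <- block[hdr_idx]
    keys <- toupper(sub("=.*$", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    get <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    pepmass <- get("PEPMASS")
    charge_raw <- get("CHARGE")
    if (is.na(pepmass) || is.na(charge_raw)) {
      skipped <- skipped + 1L
      next
    }
    pmz <- suppressWarnings(as.numeric(strsplit(trimws(pepmass), "\\s+")[[1]][1]))
    charge <- suppressWarnings(parse_mgf_charge(charge_raw))
    if (is.na(pmz) || pmz <= 0 || is.na(charge) || charge < 1 || charge > 8) {
      skipped <- skipped + 1L
      next
    }
    peak_lines <- block[!hdr_idx & nzchar(trimws(block))]
    pk <- parse_peak_lines(peak_lines)
    title <- get("TITLE")
    rt <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    nce <- suppressWarnings(as.numeric(get("NCE")))
    kept <- kept + 1L
    out[[kept]] <- spectrum(
      id = if (is.na(title)) sprintf("index=%d", k) else title,
      mz = pk$mz, intensity = pk$intensity,
      precursor_mz = pmz, charge = charge,
      collision_energy = nce, retention_time = rt
    )
  }
  out <- out[seq_len(kept)]
  if (skipped > 0L) {
    warning(sprintf("read_mgf: skipped %d unparseable record(s) in %s", skipped, path))
  }
  attr(out, "skipped") <- skipped
  out
}

# "2+", "+2", "2", "3-" -> signed integer charge (magnitude used downstream)
parse_mgf_charge <- function(x) {
  x <- trimws(x)
  sign <- if (grepl("-", x, fixed = TRUE)) -1L else 1L
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", x)))
  if (is.na(num)) return(NA_integer_)
  abs(num) * sign
}

parse_peak_lines <- function(peak_lines) {
  if (length(peak_lines) == 0L) {
    return(list(mz = numeric(0), intensity = numeric(0)))
  }
  fields <- strsplit(trimws(peak_lines), "[ \t]+")
  mz <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1])), numeric(1))
  it <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2])), numeric(1))
  ok <- !is.na(mz) & !is.na(it)
  list(mz = mz[ok], intensity = it[ok])
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] for the fields this package uses. m/z values are
#' written with six, intensities with four decimal places.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    }
    if (!is.na(s$collision_energy)) {
      writeLines(sprintf("NCE=%.2f", s$collision_energy), con)
    }
    if (length(s$mz)) {
      writeLines(sprintf("%.6f %.4f", s$mz, s$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read MS2 spectra from an mzML file
#'
#' Thin adapter over \pkg{mzR} (required for this function only). Only MS
#' level 2 scans are returned; centroided peaks are assumed. Scans without a
#' precursor charge in 1..8 are skipped and counted.
#'
#' @param path Path to an mzML file.
#' @return As [read_mgf()].
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("read_mzml requires the 'mzR' package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  ms2 <- which(hd$msLevel == 2L)
  skipped <- 0L
  out <- list()
  for (i in ms2) {
    charge <- hd$precursorCharge[i]
    pmz <- hd$precursorMZ[i]
    if (is.na(charge) || charge < 1 || charge > 8 || is.na(pmz) || pmz <= 0) {
      skipped <- skipped + 1L
      next
    }
    pk <- mzR::peaks(handle, i)
    out[[length(out) + 1L]] <- spectrum(
      id = sprintf("scan=%d", hd$acquisitionNum[i]),
      mz = pk[, 1], intensity = pk[, 2],
      precursor_mz = pmz, charge = as.integer(charge),
      collision_energy = if ("collisionEnergy" %in% names(hd)) hd$collisionEnergy[i] else NA_real_,
      retention_time = hd$retentionTime[i]
    )
  }
  if (skipped > 0L) {
    warning(sprintf("read_mzml: skipped %d MS2 scan(s) in %s", skipped, path))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read a ground-truth table
#'
#' Two-column tab-separated file `spectrum_id<TAB>peptide` (no header).
#' Entries whose peptide fails validation (unknown residues or length > 30)
#' are dropped with a warning and counted.
#'
#' @param path Path to the TSV file.
#' @return Named character vector: names are spectrum ids, values peptides,
#'   with attribute `"dropped"`.
#' @export
read_ground_truth <- function(path) {
  tb <- read.delim(path, header = FALSE, colClasses = "character",
                   col.names = c("spectrum_id", "peptide"))
  ok <- is_valid_peptide(tb$peptide)
  if (any(!ok)) {
    warning(sprintf("read_ground_truth: dropped %d invalid peptide(s)", sum(!ok)))
  }
  out <- tb$peptide[ok]
  names(out) <- tb$spectrum_id[ok]
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Write a ground-truth table
#' @param truth Named character vector (names = spectrum ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(
    data.frame(spectrum_id = names(truth), peptide = as.character(truth)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Write sequencing results
#'
#' Tab-separated with a header; one row per input spectrum in input order.
#' Columns: `spectrum_id`, `peptide`, `quality_score`, `theoretical_mass`,
#' `ppm_to_precursor`, `rescued`, `passed_mass_filter`, and the per-position
#' residue probabilities semicolon-joined in `position_probs`.
#'
#' @param results A data frame as returned by [predict.convnovo()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- data.frame(
    spectrum_id = results$spectrum_id,
    peptide = results$peptide,
    quality_score = sprintf("%.6g", results$quality_score),
    theoretical_mass = sprintf("%.6f", results$theoretical_mass),
    ppm_to_precursor = sprintf("%.6f", results$ppm_to_precursor),
    rescued = results$rescued,
    passed_mass_filter = results$passed_mass_filter,
    position_probs = vapply(
      results$position_probs,
      function(p) paste(sprintf("%.6g", p), collapse = ";"),
      character(1)
    ),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a sequencing-result table written by [write_results()]
#' @param path Path to the results TSV.
#' @return Data frame with the same columns (`position_probs` as a list of
#'   numeric vectors).
#' @export
read_results <- function(path) {
  df <- read.delim(path, header = TRUE, colClasses = "character")
  data.frame(
    spectrum_id = df$spectrum_id,
    peptide = df$peptide,
    quality_score = as.numeric(df$quality_score),
    theoretical_mass = as.numeric(df$theoretical_mass),
    ppm_to_precursor = as.numeric(df$ppm_to_precursor),
    rescued = as.logical(df$rescued),
    passed_mass_filter = as.logical(df$passed_mass_filter),
    position_probs = I(lapply(strsplit(df$position_probs, ";", fixed = TRUE),
                              as.numeric)),
    stringsAsFactors = FALSE
  )
}

#' Filter spectra and ground truth for training/evaluation
#'
#' Keeps spectra with charge 1..8 that have a valid ground-truth peptide of
#' length at most 30, mirroring the dataset-construction rules used for the
#' model (counts of dropped records are attached as attributes).
#'
#' @param spectra List of [spectrum()] objects.
#' @param truth Named character vector (ids to peptides); may be `NULL` to
#'   filter on spectrum properties alone.
#' @return List with elements `spectra` and `truth` (aligned), plus attributes
#'   `n_dropped_charge` and `n_dropped_truth`.
#' @export
filter_spectra <- function(spectra, truth = NULL) {
  charges <- vapply(spectra, `[[`, integer(1), "charge")
  keep <- charges >= 1L & charges <= 8L
  n_charge <- sum(!keep)
  spectra <- spectra[keep]
  n_truth <- 0L
  if (!is.null(truth)) {
    ids <- vapply(spectra, `[[`, character(1), "id")
    pep <- truth[ids]
    ok <- !is.na(pep) & is_valid_peptide(ifelse(is.na(pep), "", pep))
    n_truth <- sum(!ok)
    spectra <- spectra[ok]
    truth <- pep[ok]
  }
  structure(
    list(spectra = spectra, truth = truth),
    n_dropped_charge = n_charge, n_dropped_truth = n_truth
  )
}
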