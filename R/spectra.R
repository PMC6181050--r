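# MS2 spectrum I/O (MGF as a first-class text dialect; mzML through mzR),
# charge deconvolution to neutral fragment masses, and detection of
# light/heavy precursor pairs from an isotope-coded linker.

#' Construct an MS2 spectrum object
#'
#' @param scan_id Scan identifier (string).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (integer >= 1).
#' @param mz,intensity Fragment peak arrays (same length); stored sorted by
#'   m/z.
#' @param retention_time Retention time in seconds, or `NA`.
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(scan_id, precursor_mz, precursor_charge,
                         mz, intensity, retention_time = NA_real_) {
  stopifnot(length(mz) == length(intensity), precursor_charge >= 1L)
  ord <- order(mz)
  structure(list(scan_id = as.character(scan_id),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord]),
                 retention_time = retention_time),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s> precursor %0.4f m/z (%d+), %d peaks\n",
              x$scan_id, x$precursor_mz, x$precursor_charge, length(x$mz)))
  invisible(x)
}

#' Neutral mass from m/z and charge
#'
#' `M = z * mz - z * 1.00727646` (removal of `z` protons).
#'
#' @param mz Observed m/z value(s).
#' @param z Charge (integer >= 1), recycled against `mz`.
#' @return Neutral mass(es) in Da.
#' @examples
#' neutral_mass(500, 2)  # 997.98545
#' @export
neutral_mass <- function(mz, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  z * mz - z * .PROTON
}

#' m/z of a neutral mass at a given charge
#'
#' Inverse of [neutral_mass()].
#' @param m Neutral mass(es) in Da.
#' @param z Charge (>= 1).
#' @return m/z value(s).
#' @export
mass_to_mz <- function(m, z) {
  if (any(z < 1)) stop("charge must be >= 1", call. = FALSE)
  (m + z * .PROTON) / z
}

#' Read MS2 spectra from MGF or mzML
#'
#' MS2 scans only. Scans without an assigned precursor charge are dropped
#' and the drop count reported via `message()` and the `"dropped"` attribute.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"mgf"` or `"mzml"`.
#' @return A list of [ms2_spectrum()] objects with attribute `dropped`.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mgf") "mgf" else "mzml"
  }
  if (format == "mgf") read_mgf(path) else read_mzml(path)
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path, call. = FALSE)
  out <- list(); dropped <- 0L
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    ch <- getv("CHARGE")
    if (is.na(ch)) { dropped <- dropped + 1L; next }
    z <- as.integer(sub("\\+$", "", ch))
    pep <- as.numeric(strsplit(getv("PEPMASS"), "\\s+")[[1L]][1L])
    title <- getv("TITLE"); if (is.na(title)) title <- sprintf("scan=%d", k)
    rt <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    pk <- block[!kv & nzchar(block)]
    if (length(pk) > 0L) {
      m <- do.call(rbind, lapply(strsplit(pk, "\\s+"), function(x)
        as.numeric(x[1:2])))
    } else m <- matrix(numeric(), ncol = 2L)
    out[[length(out) + 1L]] <-
      ms2_spectrum(title, pep, z, m[, 1L], m[, 2L], rt)
  }
  if (dropped > 0L)
    message("read_mgf: dropped ", dropped, " scan(s) without assigned charge")
  attr(out, "dropped") <- dropped
  out
}

#' @rdname read_spectra
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  out <- list(); dropped <- 0L
  for (i in seq_len(nrow(h))) {
    if (h$msLevel[i] != 2L) next
    z <- h$precursorCharge[i]
    if (is.na(z) || z < 1L) { dropped <- dropped + 1L; next }
    pk <- mzR::peaks(f, i)
    rt <- if ("retentionTime" %in% names(h)) h$retentionTime[i] else NA_real_
    if (!is.na(rt) && rt == 0) rt <- NA_real_
    out[[length(out) + 1L]] <-
      ms2_spectrum(sprintf("scan=%d", h$acquisitionNum[i]),
                   h$precursorMZ[i], z, pk[, 1L], pk[, 2L], rt)
  }
  if (dropped > 0L)
    message("read_mzml: dropped ", dropped, " scan(s) without assigned charge")
  attr(out, "dropped") <- dropped
  out
}

#' Write MS2 spectra to MGF
#'
#' @param spectra A list of [ms2_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", sp$scan_id), con)
    writeLines(sprintf("PEPMASS=%.8f", sp$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    if (!is.na(sp$retention_time))
      writeLines(sprintf("RTINSECONDS=%.3f", sp$retention_time), con)
    if (length(sp$mz) > 0L)
      writeLines(sprintf("%.8f %.4f", sp$mz, sp$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

.b64_doubles <- function(x)
  gsub("\n", "", jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                               size = 8L,
                                               endian = "little")),
       fixed = TRUE)

#' Write MS2 spectra to a minimal mzML file
#'
#' Emits uncompressed 64-bit float arrays in a plain (non-indexed) mzML 1.1.0
#' document readable by standard mzML parsers.
#'
#' @param spectra A list of [ms2_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" ',
    'URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/></cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<softwareList count="1"><software id="xlscout" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="ic"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="xlscout"/></dataProcessing>',
    '</dataProcessingList>',
    sprintf('<run id="run" defaultInstrumentConfigurationRef="ic">'),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp">',
            length(spectra))), con)
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    bmz <- .b64_doubles(sp$mz); bint <- .b64_doubles(sp$intensity)
    rt <- if (is.na(sp$retention_time)) "" else sprintf(
      '<scanList count="1"><scan><cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitName="second"/></scan></scanList>',
      sp$retention_time)
    writeLines(sprintf(paste0(
      '<spectrum index="%d" id="%s" defaultArrayLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>',
      '%s',
      '<precursorList count="1"><precursor>',
      '<selectedIonList count="1"><selectedIon>',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.8f"/>',
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'),
      i - 1L, sp$scan_id, length(sp$mz), rt, sp$precursor_mz,
      sp$precursor_charge, nchar(bmz), bmz, nchar(bint), bint), con)
  }
  writeLines('</spectrumList></run></mzML>', con)
  invisible(path)
}

#' Deconvolute an MS2 spectrum to neutral fragment masses
#'
#' Each peak is interpreted at every plausible fragment charge
#' `1..max_fragment_charge`; hypotheses above the precursor neutral mass
#' (plus tolerance) are discarded, and hypotheses agreeing within
#' `merge_tol_da` are merged keeping the most intense representative.
#' The result is deterministic.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param max_fragment_charge Maximum fragment charge considered; default is
#'   `precursor_charge - 1` (at least 1).
#' @param merge_tol_da Merge tolerance in Da.
#' @return A list of class `neutral_peaks` with `scan_id`,
#'   `precursor_neutral_mass`, `mass` (sorted ascending) and `intensity`.
#' @export
deconvolute <- function(spectrum, max_fragment_charge = NULL,
                        merge_tol_da = 0.01) {
  if (is.null(max_fragment_charge) || is.na(max_fragment_charge))
    max_fragment_charge <- max(1L, spectrum$precursor_charge - 1L)
  pm <- neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
  zs <- seq_len(max_fragment_charge)
  m <- as.vector(outer(spectrum$mz, zs, neutral_mass))
  inten <- rep(spectrum$intensity, times = length(zs))
  keep <- m > 0 & m <= pm + merge_tol_da
  m <- m[keep]; inten <- inten[keep]
  ord <- order(m, -inten)
  m <- m[ord]; inten <- inten[ord]
  if (length(m) > 1L) {
    grp <- cumsum(c(TRUE, diff(m) > merge_tol_da))
    best <- tapply(seq_along(m), grp, function(ix) ix[which.max(inten[ix])])
    best <- sort(as.integer(best))
    m <- m[best]; inten <- inten[best]
  }
  structure(list(scan_id = spectrum$scan_id, precursor_neutral_mass = pm,
                 mass = m, intensity = inten),
            class = "neutral_peaks")
}

#' @export
print.neutral_peaks <- function(x, ...) {
  cat(sprintf("<neutral_peaks %s> precursor %0.4f Da, %d neutral masses\n",
              x$scan_id, x$precursor_neutral_mass, length(x$mass)))
  invisible(x)
}

#' Detect light/heavy precursor pairs
#'
#' Finds pairs of spectra whose precursor neutral masses differ by `delta`
#' (default: the DSS d0/d12 shift, 12.07532 Da) within `tol_ppm` of the
#' heavier mass. When both scans carry retention times, the pair is kept
#' only if they elute within `rt_window` seconds — deuterated species
#' co-elute closely on reversed phase.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param delta Mass difference in Da.
#' @param tol_ppm Tolerance (ppm of the heavy neutral mass).
#' @param rt_window Retention-time window in seconds.
#' @return A data.frame with columns `light_scan`, `heavy_scan`,
#'   `light_mass`, `heavy_mass`, `delta_error_ppm`.
#' @export
pair_precursors <- function(spectra, delta = cross_linker("DSS")$heavy_delta,
                            tol_ppm = 10, rt_window = 60) {
  n <- length(spectra)
  masses <- vapply(spectra, function(s)
    neutral_mass(s$precursor_mz, s$precursor_charge), numeric(1L))
  rts <- vapply(spectra, function(s) s$retention_time, numeric(1L))
  ids <- vapply(spectra, function(s) s$scan_id, character(1L))
  res <- data.frame(light_scan = character(), heavy_scan = character(),
                    light_mass = numeric(), heavy_mass = numeric(),
                    delta_error_ppm = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(res)
  ord <- order(masses)
  for (ii in seq_len(n - 1L)) {
    i <- ord[ii]
    for (jj in (ii + 1L):n) {
      j <- ord[jj]
      d <- masses[j] - masses[i]
      if (d > delta + masses[j] * tol_ppm * 1e-6) break
      if (abs(d - delta) <= masses[j] * tol_ppm * 1e-6) {
        if (!is.na(rts[i]) && !is.na(rts[j]) &&
            abs(rts[i] - rts[j]) > rt_window) next
        res[nrow(res) + 1L, ] <- list(ids[i], ids[j], masses[i], masses[j],
                                      (d - delta) / masses[j] * 1e6)
      }
    }
  }
  res[order(res$light_mass, res$light_scan), , drop = FALSE]
}
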