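# Sequence I/O, carbon counting, monoisotopic mass arithmetic and tryptic
# digestion. Protein sets are plain data.frames (one row per protein);
# peptides likewise (one row per peptide), so downstream modules can index
# and join without bespoke containers.

.CANONICAL <- names(.RESIDUE_MASS)

.check_canonical <- function(sequence, what = "sequence") {
  chars <- strsplit(sequence, "", fixed = TRUE)
  bad <- lapply(chars, function(ch) unique(ch[!ch %in% .CANONICAL]))
  offending <- which(lengths(bad) > 0L)
  if (length(offending) > 0L)
    stop(what, " contains non-canonical residue(s): ",
         paste(unlist(bad[offending]), collapse = ", "),
         " (entry ", offending[1L], ")", call. = FALSE)
  invisible(TRUE)
}

#' Read a protein FASTA file
#'
#' Reads mature protein sequences into a data.frame, validating that every
#' sequence uses only the 20 canonical one-letter codes. Record ids are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the description. Order is preserved and duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "MKPRLYKAR", ">p2", "GASPK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence for id ",
                               ids[!nzchar(seqs)][1L], call. = FALSE)
  .check_canonical(seqs, "sequence")
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteins A data.frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  hdr <- proteins$id
  if (!is.null(proteins$description))
    hdr <- ifelse(nzchar(proteins$description),
                  paste(hdr, proteins$description), hdr)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Count carbon atoms in a polypeptide
#'
#' Total carbon atoms of the intact polypeptide: the sum of the residue
#' formula carbons. Peptide-bond condensation removes only water, which
#' carries no carbon, so the count is additive over concatenation. Used to
#' convert uniform-label densitometry signal (proportional to copies x
#' carbons) into relative molar amounts.
#'
#' @param sequence Amino acid sequence(s), canonical letters only.
#' @return Integer vector of carbon counts (`0` for the empty string).
#' @examples
#' carbon_count("G")  # glycine C2H5NO2 -> 2
#' carbon_count("W")  # tryptophan C11H12N2O2 -> 11
#' @export
carbon_count <- function(sequence) {
  .check_canonical(sequence)
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) sum(.RESIDUE_CARBON[ch]), integer(1L),
         USE.NAMES = FALSE)
}

#' Monoisotopic mass of a peptide
#'
#' Sum of residue masses plus one water, plus any modification mass deltas.
#' Methionine oxidation (+15.994915 Da) is the only variable modification the
#' search uses, but any delta can be supplied.
#'
#' @param sequence Peptide sequence (single string, canonical letters).
#' @param modifications Optional data.frame with columns `position` (1-based
#'   within the peptide) and `delta` (Da); or `NULL`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mono_mass("AG")  # 71.03711 + 57.02146 + 18.010565
#' @export
peptide_mono_mass <- function(sequence, modifications = NULL) {
  stopifnot(length(sequence) == 1L)
  if (!nzchar(sequence)) return(.WATER)
  .check_canonical(sequence)
  m <- sum(.RESIDUE_MASS[strsplit(sequence, "", fixed = TRUE)[[1L]]]) + .WATER
  if (!is.null(modifications) && nrow(modifications) > 0L) {
    if (any(modifications$position < 1L |
            modifications$position > nchar(sequence)))
      stop("modification position outside peptide", call. = FALSE)
    m <- m + sum(modifications$delta)
  }
  m
}

# Positions immediately after which trypsin cleaves: K or R not followed by P.
.cleavage_sites <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) return(integer())
  which(ch[-n] %in% c("K", "R") & ch[-1L] != "P")
}

#' In silico tryptic digestion
#'
#' Cleaves after K/R except when the next residue is P, and emits every
#' peptide with at most `max_missed` internal (missed) cleavage sites and a
#' length within `[min_len, max_len]`. Positions are 1-based inclusive in the
#' mature protein. Cross-linked lysines suppress cleavage in practice, so
#' cross-link searches default to several missed cleavages.
#'
#' @param protein A one-row data.frame (or list) with `id` and `sequence`.
#' @param max_missed Maximum internal missed cleavages (>= 0).
#' @param min_len,max_len Peptide length bounds (residues).
#' @return A data.frame with columns `protein_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`, `protein_length`.
#' @examples
#' digest(list(id = "p", sequence = "MKPRLYKAR"), max_missed = 1)
#' @export
digest <- function(protein, max_missed = 3L, min_len = 1L, max_len = 60L) {
  stopifnot(max_missed >= 0L)
  seqc <- protein$sequence
  n <- nchar(seqc)
  sites <- .cleavage_sites(seqc)
  bounds <- c(0L, sites, n)                     # peptide boundaries
  nb <- length(bounds)
  starts <- integer(); ends <- integer(); missed <- integer()
  for (i in seq_len(nb - 1L)) {
    jmax <- min(nb, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[j])
      missed <- c(missed, j - i - 1L)
    }
  }
  len <- ends - starts + 1L
  keep <- len >= min_len & len <= max_len
  data.frame(
    protein_id = rep(protein$id, sum(keep)),
    start = starts[keep], end = ends[keep],
    sequence = substring(seqc, starts[keep], ends[keep]),
    missed_cleavages = missed[keep],
    protein_length = rep(n, sum(keep)),
    stringsAsFactors = FALSE
  )
}

#' Digest a whole protein database into an indexed peptide table
#'
#' Runs [digest()] over every protein and annotates each peptide with its
#' neutral monoisotopic mass and its valid cross-link attachment sites for
#' `linker`. The returned table is sorted by mass, which is what
#' [enumerate_candidates()] binary-searches.
#'
#' @param proteins A data.frame from [read_fasta()].
#' @param linker A [cross_linker()] used to precompute link sites.
#' @param max_missed,min_len,max_len Passed to [digest()].
#' @param oxidize_met Also index singly Met-oxidized variants (+15.994915 Da,
#'   the search's only variable modification); one variant per methionine.
#' @return A data.frame sorted by `mass` with the [digest()] columns plus
#'   `mass` (Da), `link_sites` (semicolon-joined 1-based positions, "" when
#'   none), `n_sites` and `mod_pos` (position of the oxidized Met within the
#'   peptide, `NA` for the unmodified form).
#' @export
peptide_index <- function(proteins, linker = cross_linker("DSS"),
                          max_missed = 3L, min_len = 4L, max_len = 60L,
                          oxidize_met = TRUE) {
  peps <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], max_missed = max_missed,
           min_len = min_len, max_len = max_len)))
  if (is.null(peps) || nrow(peps) == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      missed_cleavages = integer(), protein_length = integer(),
                      mass = numeric(), link_sites = character(),
                      n_sites = integer(), mod_pos = integer(),
                      stringsAsFactors = FALSE))
  peps$mass <- vapply(peps$sequence, peptide_mono_mass, numeric(1L),
                      USE.NAMES = FALSE)
  sites <- lapply(seq_len(nrow(peps)), function(i)
    link_sites(peps[i, ], linker))
  peps$link_sites <- vapply(sites, paste, character(1L), collapse = ";")
  peps$n_sites <- lengths(sites)
  peps$mod_pos <- NA_integer_
  if (oxidize_met) {
    mox <- mass_constants()$met_oxidation
    extra <- lapply(which(grepl("M", peps$sequence, fixed = TRUE)),
                    function(i) {
      at <- which(strsplit(peps$sequence[i], "", fixed = TRUE)[[1L]] == "M")
      v <- peps[rep(i, length(at)), , drop = FALSE]
      v$mod_pos <- at
      v$mass <- v$mass + mox
      v
    })
    peps <- rbind(peps, do.call(rbind, extra))
  }
  mp <- ifelse(is.na(peps$mod_pos), 0L, peps$mod_pos)
  peps <- peps[order(peps$mass, peps$protein_id, peps$start, mp), ,
               drop = FALSE]
  rownames(peps) <- NULL
  peps
}

#' Write a peptide table as TSV
#'
#' @param peptides A data.frame from [digest()] or [peptide_index()].
#' @param path Output path.
#' @param config Optional resolved configuration echoed into `#` headers.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path, config = NULL) {
  write_tsv_report(peptides, path, config)
}
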