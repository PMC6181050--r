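# Subunit adjacency from cross-link evidence, peptide-to-chain mapping, and
# C-alpha distance restraints on structural models.

#' Read a cross-linked product table
#'
#' @param path TSV with columns `record_id`, `members` (semicolon list),
#'   and optionally `apparent_kd`, `linkers`, `methods`.
#' @return A data.frame of cross-link records.
#' @export
read_crosslink_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("record_id", "members")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("cross-link table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Packaged cross-linked products of the PSI-LHCI supercomplex
#'
#' The curated table of 22 cross-linked products detected for the
#' Chlamydomonas reinhardtii PSI-LHCI supercomplex (immunoblot and/or mass
#' spectrometry, DSS/DSG/EDC/DMS chemistry), shipped with the package.
#'
#' @return A data.frame of cross-link records (see [read_crosslink_table()]).
#' @export
psi_lhci_crosslinks <- function() {
  read_crosslink_table(system.file("extdata",
                                   "psi_lhci_crosslinked_products.tsv",
                                   package = "xlscout", mustWork = TRUE))
}

#' Build the subunit adjacency hypergraph
#'
#' One hyperedge per cross-linked product; the node set is the union of all
#' members. Products joining three subunits remain a single hyperedge and
#' are expanded to flagged pairs only in [pairwise_edges()].
#'
#' @param records A data.frame with `record_id` and `members`
#'   (semicolon-joined), e.g. [psi_lhci_crosslinks()] or validated search
#'   output with a `members` column.
#' @return An object of class `topology_graph`: list with `nodes` (sorted
#'   character vector) and `hyperedges` (data.frame `record_id`, `members`,
#'   `n_members`, plus any extra columns of `records`).
#' @export
build_topology_graph <- function(records) {
  if (anyDuplicated(records$record_id))
    stop("duplicate record ids", call. = FALSE)
  mem <- lapply(records$members, .members)
  if (any(lengths(mem) < 2L))
    stop("cross-link record with fewer than 2 members: ",
         paste(records$record_id[lengths(mem) < 2L], collapse = ", "),
         call. = FALSE)
  edges <- records
  edges$n_members <- lengths(mem)
  structure(list(nodes = sort(unique(unlist(mem))), hyperedges = edges),
            class = "topology_graph")
}

#' @export
print.topology_graph <- function(x, ...) {
  cat(sprintf("<topology_graph> %d subunits, %d cross-linked products (%d pairs, %d higher-order)\n",
              length(x$nodes), nrow(x$hyperedges),
              sum(x$hyperedges$n_members == 2L),
              sum(x$hyperedges$n_members > 2L)))
  invisible(x)
}

#' Pairwise projection of a topology graph
#'
#' Expands each hyperedge to all unordered member pairs; pairs arising from
#' a higher-order (3-subunit) product are flagged, since the product itself
#' does not prove every pairwise contact.
#'
#' @param graph A [build_topology_graph()] object.
#' @return A data.frame `record_id`, `subunit_a`, `subunit_b`,
#'   `from_higher_order`.
#' @export
pairwise_edges <- function(graph) {
  out <- list()
  for (i in seq_len(nrow(graph$hyperedges))) {
    m <- sort(.members(graph$hyperedges$members[i]))
    pr <- utils::combn(m, 2L)
    out[[i]] <- data.frame(
      record_id = graph$hyperedges$record_id[i],
      subunit_a = pr[1L, ], subunit_b = pr[2L, ],
      from_higher_order = length(m) > 2L,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export a topology graph in DOT format
#'
#' @param graph A [build_topology_graph()] object.
#' @param path Output path; `NULL` returns the DOT text.
#' @return The DOT lines, invisibly when written to `path`.
#' @export
as_dot <- function(graph, path = NULL) {
  pe <- pairwise_edges(graph)
  lines <- c("graph topology {",
             paste0('  "', graph$nodes, '";'),
             sprintf('  "%s" -- "%s"%s;', pe$subunit_a, pe$subunit_b,
                     ifelse(pe$from_higher_order, ' [style=dashed]', '')),
             "}")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Map a cross-linked peptide onto a structure chain
#'
#' Locates the peptide in the chain sequence, preferring an exact substring
#' match; otherwise the best gapless sliding alignment with at least
#' `min_identity` identity over the peptide length. Several equally good
#' placements are an ambiguity error.
#'
#' @param peptide Peptide sequence.
#' @param link_pos 1-based position of the linked residue in the peptide.
#' @param chain_seq The chain's one-letter sequence.
#' @param min_identity Identity threshold for inexact placement.
#' @return A list `chain_pos` (1-based residue index in the chain of the
#'   linked residue), `identity`, `method` ("exact"/"aligned"); or `NULL`
#'   when no placement reaches the threshold.
#' @export
map_peptide_to_chain <- function(peptide, link_pos, chain_seq,
                                 min_identity = 0.6) {
  np <- nchar(peptide); nc <- nchar(chain_seq)
  stopifnot(link_pos >= 1L, link_pos <= np)
  if (np > nc) return(NULL)
  hits <- gregexpr(peptide, chain_seq, fixed = TRUE)[[1L]]
  if (hits[1L] != -1L) {
    if (length(hits) > 1L)
      stop("ambiguous placement: exact match at positions ",
           paste(hits, collapse = ", "), call. = FALSE)
    return(list(chain_pos = as.integer(hits[1L]) + link_pos - 1L,
                identity = 1, method = "exact"))
  }
  pch <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  cch <- strsplit(chain_seq, "", fixed = TRUE)[[1L]]
  starts <- seq_len(nc - np + 1L)
  ident <- vapply(starts, function(s)
    sum(pch == cch[s:(s + np - 1L)]) / np, numeric(1L))
  best <- max(ident)
  if (best < min_identity) return(NULL)
  at <- starts[ident == best]
  if (length(at) > 1L)
    stop("ambiguous placement: identity ", round(best, 3),
         " at positions ", paste(at, collapse = ", "), call. = FALSE)
  list(chain_pos = at + link_pos - 1L, identity = best, method = "aligned")
}

#' Read a structure (PDB or mmCIF)
#'
#' @param path Structure file; format chosen by extension (`.cif`/`.mmcif`
#'   use the mmCIF reader, anything else PDB).
#' @return A `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
  else bio3d::read.pdb(path)
}

#' One-letter polymer sequences per chain of a structure
#'
#' @param structure A `bio3d` `pdb` object.
#' @return Named character vector (one sequence per chain).
#' @export
chain_sequences <- function(structure) {
  ca <- structure$atom[structure$atom$elety == "CA" &
                         structure$atom$type == "ATOM", , drop = FALSE]
  vapply(split(ca, ca$chain), function(d) {
    d <- d[order(d$resno), , drop = FALSE]
    paste(bio3d::aa321(d$resid), collapse = "")
  }, character(1L))
}

.ca_xyz <- function(structure, chain, resno) {
  sel <- structure$atom$elety == "CA" & structure$atom$chain == chain &
    structure$atom$resno == resno & structure$atom$type == "ATOM"
  if (!any(sel))
    stop("no C-alpha atom for chain ", chain, " residue ", resno,
         call. = FALSE)
  as.numeric(structure$atom[which(sel)[1L], c("x", "y", "z")])
}

#' Check a C-alpha distance restraint between two mapped residues
#'
#' Computes the Euclidean distance between the C-alpha atoms of the two
#' mapped residues; the restraint is satisfied when the distance does not
#' exceed `threshold` (default 30 Angstrom for DSS). Distances in the
#' 26-30 Angstrom band are additionally flagged as near the limit.
#'
#' @param structure A `bio3d` `pdb` object (see [read_structure()]).
#' @param chain_a,resno_a Chain id and residue number of the first linked
#'   residue (structure numbering).
#' @param chain_b,resno_b Same for the second residue.
#' @param threshold Maximum compatible C-alpha distance (Angstrom).
#' @param soft_band Lower edge of the reported near-limit band (Angstrom).
#' @param record_id Optional identifier echoed into the result.
#' @return A data.frame row: `record_id`, `chain_a`, `resno_a`, `chain_b`,
#'   `resno_b`, `distance`, `threshold`, `satisfied`, `near_limit`.
#' @export
check_restraint <- function(structure, chain_a, resno_a, chain_b, resno_b,
                            threshold = 30, soft_band = 26,
                            record_id = NA_character_) {
  d <- sqrt(sum((.ca_xyz(structure, chain_a, resno_a) -
                   .ca_xyz(structure, chain_b, resno_b))^2))
  data.frame(record_id = record_id, chain_a = chain_a, resno_a = resno_a,
             chain_b = chain_b, resno_b = resno_b, distance = d,
             threshold = threshold, satisfied = d <= threshold,
             near_limit = d > soft_band & d <= threshold,
             stringsAsFactors = FALSE)
}
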