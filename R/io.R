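#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

AA_SYMBOLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an aligned FASTA file into a sequence tibble
#'
#' Sequences are returned one row per record, in file order, upper-cased.
#' All records must have equal length (the file is an alignment); a ragged
#' file is an error naming the first offending record. In amino-acid mode the
#' residue alphabet is the 20 standard amino acids plus `-` (gap) and `X`
#' (unknown); a `*` (stop) is rejected because alignments here hold mature
#' peptides. In nucleotide mode the alphabet is `A C G T N -`.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return A tibble with columns `id`, `seq` and attribute `type`; every
#'   `seq` has the same number of characters (`aln_length()`).
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  new_alignment(tibble(id = ids, seq = unname(seqs)), type = type)
}

#' Construct an alignment tibble from ids and sequences
#'
#' @param x A data frame with columns `id` and `seq`.
#' @param type `"AA"` or `"DNA"`.
#' @return The validated tibble with attribute `type`.
#' @export
new_alignment <- function(x, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- as_tibble(x[, c("id", "seq")])
  if (nrow(x) == 0) abort("alignment has no records")
  if (any(!nzchar(x$id))) abort("empty sequence id")
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(unique(dup), collapse = ", ")))
  }
  lens <- nchar(x$seq)
  if (any(lens == 0)) abort(paste0("empty sequence: ", x$id[lens == 0][1]))
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    abort(paste0("ragged alignment: record ", bad, " ('", x$id[bad],
                 "') has length ", lens[bad], ", expected ", lens[1]))
  }
  alphabet <- if (type == "AA") c(AA_SYMBOLS, "-", "X") else c("A", "C", "G", "T", "N", "-")
  found <- unique(strsplit(paste(x$seq, collapse = ""), "")[[1]])
  bad <- setdiff(found, alphabet)
  if (length(bad) > 0) {
    abort(paste0("invalid ", if (type == "AA") "residue" else "base",
                 " symbol(s): ", paste(bad, collapse = " ")))
  }
  attr(x, "type") <- type
  class(x) <- c("mb_aln", class(x))
  x
}

#' Number of columns (sites) in an alignment
#' @param aln An alignment tibble from [read_fasta()] or [new_alignment()].
#' @return Integer site count.
#' @export
aln_length <- function(aln) nchar(aln$seq[1])

#' Alignment as a character matrix (rows = records, 1-based site columns)
#' @param aln An alignment tibble.
#' @return Character matrix with rownames = ids.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

#' Write an alignment tibble to FASTA
#'
#' @param aln Alignment tibble.
#' @param path Output file.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", aln$id[i]), con)
    s <- aln$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code. With both `drop_init_met` and `drop_stop` set, a
#' complete CDS of 3*(N+2) nt yields the N-residue mature peptide (paper-style
#' mature numbering: position 1 is the first residue after the initiator Met).
#' Internal stop codons are flagged, not dropped: they signal a pseudogene.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param id Record id for the returned row.
#' @param drop_init_met Drop the initiator methionine (default TRUE).
#' @param drop_stop Drop the terminal stop codon (default TRUE); a warning is
#'   raised if the final codon is not a stop.
#' @return One-row tibble: `id`, `seq` (protein), `n_residues`,
#'   `premature_stop` (logical).
#' @export
translate_cds <- function(cds, id = "cds", drop_init_met = TRUE, drop_stop = TRUE) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) {
    abort(paste0("CDS length ", nchar(cds), " is not divisible by 3"))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  res <- strsplit(aa, "")[[1]]
  if (drop_stop) {
    if (res[length(res)] == "*") {
      res <- res[-length(res)]
    } else {
      warn("drop_stop set but final codon is not a stop codon")
    }
  }
  if (drop_init_met) {
    if (res[1] == "M") res <- res[-1] else warn("drop_init_met set but first residue is not Met")
  }
  premature <- any(res == "*")
  tibble(id = id, seq = paste(res, collapse = ""),
         n_residues = length(res), premature_stop = premature)
}

#' Read a rooted Newick tree and assign stable node identifiers
#'
#' Uses ape for parsing. The tree must be rooted (error otherwise). Branch
#' lengths must be non-negative. Internal nodes keep their labels when
#' present; unlabelled internal nodes get stable ids `N<k>` numbered by ape's
#' internal node index. Polytomies are accepted.
#'
#' @param path Newick file.
#' @return An ape `phylo` with non-empty `node.label`.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(paste0("could not parse Newick file: ", path))
  prepare_tree(tr)
}

#' Validate a phylo object and assign stable internal-node ids
#' @param tr An ape `phylo`.
#' @return The tree with complete `node.label`.
#' @export
prepare_tree <- function(tr) {
  if (!inherits(tr, "phylo")) abort("expected an ape 'phylo' object")
  if (!ape::is.rooted(tr)) abort("tree is unrooted; root it before use")
  if (anyDuplicated(tr$tip.label)) abort("duplicate tip labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    abort("negative branch length(s) in tree")
  }
  lab <- tr$node.label
  auto <- paste0("N", seq_len(tr$Nnode))
  if (is.null(lab)) {
    lab <- auto
  } else {
    empty <- is.na(lab) | !nzchar(lab)
    lab[empty] <- auto[empty]
  }
  tr$node.label <- lab
  tr
}

#' Stable node ids for every node, indexed by ape node number
#' @param tr A prepared tree (see [prepare_tree()]).
#' @return Character vector of length `Ntip + Nnode`.
#' @export
node_ids <- function(tr) c(tr$tip.label, tr$node.label)

#' Write a tree with node annotations
#'
#' Emits Newick (internal-node labels preserved) plus a sidecar TSV mapping
#' `node_id` to the annotation columns, so numeric annotations (Z_Mb,
#' posterior probabilities) survive at full precision.
#'
#' @param tr Prepared tree.
#' @param annotations Data frame with a `node_id` column.
#' @param path Output Newick path; the sidecar is `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(tr, annotations, path) {
  stopifnot("node_id" %in% names(annotations))
  unknown <- setdiff(annotations$node_id, node_ids(tr))
  if (length(unknown) > 0) {
    abort(paste0("annotation for unknown node id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  ape::write.tree(tr, file = path, digits = 10)
  utils::write.table(annotations, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tip trait table (TSV)
#'
#' Expected columns: `tip_id`, `lifestyle`, and optionally `zmb`, `mobility`.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_traits <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip_id", "lifestyle") %in% names(x))) {
    abort("trait table must have columns tip_id and lifestyle")
  }
  as_tibble(x)
}

#' Binarize a multi-state lifestyle column
#'
#' The trait table carries the four eulipotyphlan ecomorphotypes
#' (terrestrial, semi_fossorial, fossorial, semi_aquatic); every analysis here
#' works on a binary derived/other coding obtained by naming the derived set,
#' e.g. `derived = "semi_aquatic"` or `derived = c("fossorial",
#' "semi_fossorial")` for a digging coding.
#'
#' @param traits Trait tibble with `tip_id` and `lifestyle`.
#' @param derived Character vector of lifestyle values coded 1.
#' @return Tibble `tip_id`, `state` (0/1 integer).
#' @export
binarize_lifestyle <- function(traits, derived) {
  tibble(tip_id = traits$tip_id,
         state = as.integer(traits$lifestyle %in% derived))
}
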