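# Mapping net surface charge onto a tree: per-node Z_Mb, per-branch
# charge-changing substitution lists, and an uncertainty ledger quantifying
# how reconstruction ambiguity could move Z_Mb.

#' Z_Mb at every node of a tree
#'
#' Tips take the charge of their observed sequence; internal nodes take the
#' charge of the MAP ancestral sequence (gap states included). Uncertainty
#' is reported separately ([charge_robustness()]), not integrated, so each
#' node carries the charge of a single concrete sequence.
#'
#' @param tr Rooted tree.
#' @param aln Tip alignment.
#' @param anc An `mb_anc` from [marginal_reconstruct()], or an alignment
#'   tibble of internal-node sequences (ids = node ids).
#' @param ph,pka_table,include_termini,site_pka See [net_charge()].
#' @return Tibble `node_id`, `is_tip`, `zmb`, `zmb_2dp`, ordered tips first.
#' @export
node_charges <- function(tr, aln, anc, ph = 6.5,
                         pka_table = default_pka_table(),
                         include_termini = TRUE, site_pka = NULL) {
  tr <- prepare_tree(tr)
  anc_aln <- if (inherits(anc, "mb_anc")) ancestral_sequences(anc, aln) else anc
  miss <- setdiff(tr$node.label, anc_aln$id)
  if (length(miss) > 0) {
    abort(paste0("no ancestral sequence for node(s): ", paste(miss, collapse = ", ")))
  }
  miss_tip <- setdiff(tr$tip.label, aln$id)
  if (length(miss_tip) > 0) {
    abort(paste0("no sequence for tip(s): ", paste(miss_tip, collapse = ", ")))
  }
  tips <- zmb(aln[match(tr$tip.label, aln$id), ], ph, pka_table,
              include_termini, site_pka)
  ints <- zmb(anc_aln[match(tr$node.label, anc_aln$id), ], ph, pka_table,
              include_termini, site_pka)
  dplyr::bind_rows(
    dplyr::mutate(tips, is_tip = TRUE, .after = "id"),
    dplyr::mutate(ints, is_tip = FALSE, .after = "id")
  ) |>
    dplyr::rename(node_id = "id")
}

#' Per-branch substitution list with charge classification
#'
#' Compares the sequence at each node with its parent's and reports one row
#' per differing site: residue-to-residue substitutions carry their charge
#' delta and class (increasing/decreasing/neutral at the given threshold);
#' a change to or from a gap is reported as an indel event (`event =
#' "deletion"`/`"insertion"`) whose delta is minus/plus the charge of the
#' residue involved. Sites where either state is `X` are skipped.
#'
#' @param tr Rooted tree.
#' @param node_seqs Alignment tibble covering every node id (tips and
#'   internal), e.g. tip alignment bound to [ancestral_sequences()].
#' @param ph,pka_table,site_pka See [net_charge()].
#' @param threshold Classification threshold (default 0.5).
#' @return Tibble: `parent_id`, `child_id`, `site`, `from_res`, `to_res`,
#'   `delta`, `class`, `event`; sorted by branch (postorder) then site.
#' @export
branch_substitutions <- function(tr, node_seqs, ph = 6.5,
                                 pka_table = default_pka_table(),
                                 site_pka = NULL, threshold = 0.5) {
  idx <- tree_index(tr)
  seqs <- stats::setNames(node_seqs$seq, node_seqs$id)
  miss <- setdiff(idx$ids, names(seqs))
  if (length(miss) > 0) {
    abort(paste0("missing sequence for node(s): ", paste(miss, collapse = ", ")))
  }
  if (length(unique(nchar(seqs[idx$ids]))) != 1) {
    abort("node sequences have unequal lengths")
  }
  lut <- residue_charges(ph, pka_table)
  rows <- purrr::map_dfr(seq_len(nrow(idx$edge)), function(i) {
    p <- idx$ids[idx$edge[i, 1]]; ch <- idx$ids[idx$edge[i, 2]]
    a <- strsplit(seqs[[p]], "")[[1]]
    b <- strsplit(seqs[[ch]], "")[[1]]
    diff <- which(a != b & a != "X" & b != "X")
    if (length(diff) == 0) return(NULL)
    delta <- vapply(diff, function(s) {
      substitution_delta(a[s], b[s], ph, pka_table, site = s, site_pka = site_pka)
    }, numeric(1))
    event <- ifelse(a[diff] == "-", "insertion",
                    ifelse(b[diff] == "-", "deletion", "substitution"))
    tibble(parent_id = p, child_id = ch, site = diff,
           from_res = a[diff], to_res = b[diff], delta = delta,
           class = classify_charge_change(delta, threshold), event = event)
  })
  if (nrow(rows) == 0) return(rows)
  dplyr::arrange(rows, match(.data$child_id, idx$ids[idx$edge[, 2]]), .data$site)
}

#' Per-branch summary counts of charge-changing substitutions
#'
#' @param subs Output of [branch_substitutions()].
#' @return Tibble `parent_id`, `child_id`, `n_increasing`, `n_decreasing`,
#'   `n_neutral`, `delta_total`.
#' @export
summarize_branches <- function(subs) {
  subs |>
    dplyr::group_by(.data$parent_id, .data$child_id) |>
    dplyr::summarise(
      n_increasing = sum(.data$class == "increasing"),
      n_decreasing = sum(.data$class == "decreasing"),
      n_neutral = sum(.data$class == "neutral"),
      delta_total = sum(.data$delta),
      .groups = "drop")
}

#' Uncertainty ledger for a reconstruction's effect on Z_Mb
#'
#' Classifies every internal node x site into four disjoint categories:
#' confident (MAP probability > `map_cutoff`, no alternative residue above
#' `alt_cutoff`), same-charge alternatives only, different-charge
#' alternative(s), and low-confidence MAP with no listed alternative. For
#' different-charge cases it records the summed probability of
#' alternative-charge states and the largest |delta Z_Mb| an alternative
#' choice would cause.
#'
#' @param anc An `mb_anc`.
#' @param alt_cutoff Probability above which an alternative residue counts
#'   (default 0.05).
#' @param map_cutoff MAP confidence threshold (default 0.95).
#' @param ph,pka_table See [net_charge()].
#' @param charge_threshold Same/different charge classification threshold on
#'   the residue-charge difference (default 0.5).
#' @return Object of class `mb_ledger`: `counts` tibble (category, n,
#'   percent), `cases` tibble of the different-charge node x sites
#'   (`node_id`, `site`, `map_residue`, `map_prob`, `alt_prob_sum`,
#'   `max_abs_dzmb`), `total`.
#' @export
charge_robustness <- function(anc, alt_cutoff = 0.05, map_cutoff = 0.95,
                              ph = 6.5, pka_table = default_pka_table(),
                              charge_threshold = 0.5) {
  lut <- residue_charges(ph, pka_table)[AA_SYMBOLS]
  ids <- names(anc$posterior)
  n_conf <- 0L; n_same <- 0L; n_lowconf <- 0L
  cases <- list()
  for (id in ids) {
    post <- anc$posterior[[id]]
    S <- ncol(post)
    map_i <- apply(post, 2, which.max)
    map_p <- post[cbind(map_i, seq_len(S))]
    for (s in seq_len(S)) {
      alt <- which(post[, s] > alt_cutoff)
      alt <- setdiff(alt, map_i[s])
      if (length(alt) == 0) {
        if (map_p[s] > map_cutoff) n_conf <- n_conf + 1L else n_lowconf <- n_lowconf + 1L
        next
      }
      ddelta <- lut[alt] - lut[map_i[s]]
      different <- abs(ddelta) >= charge_threshold
      if (!any(different)) {
        n_same <- n_same + 1L
      } else {
        cases[[length(cases) + 1]] <- tibble(
          node_id = id, site = s,
          map_residue = AA_SYMBOLS[map_i[s]], map_prob = map_p[s],
          alt_prob_sum = sum(post[alt[different], s]),
          max_abs_dzmb = max(abs(ddelta[different])))
      }
    }
  }
  cases <- if (length(cases)) dplyr::bind_rows(cases) else
    tibble(node_id = character(), site = integer(), map_residue = character(),
           map_prob = numeric(), alt_prob_sum = numeric(), max_abs_dzmb = numeric())
  total <- length(ids) * ncol(anc$posterior[[1]])
  counts <- tibble(
    category = c("confident", "same_charge_alternative",
                 "different_charge_alternative", "low_confidence_no_alternative"),
    n = c(n_conf, n_same, nrow(cases), n_lowconf))
  counts$percent <- 100 * counts$n / total
  out <- list(counts = counts, cases = cases, total = total,
              alt_cutoff = alt_cutoff, map_cutoff = map_cutoff)
  class(out) <- "mb_ledger"
  out
}

#' @export
print.mb_ledger <- function(x, ...) {
  cat(sprintf("Reconstruction-uncertainty ledger over %d node x site cells:\n", x$total))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-32s %6d (%5.2f%%)\n", x$counts$category[i],
                x$counts$n[i], x$counts$percent[i]))
  }
  invisible(x)
}

#' Tidy the uncertainty ledger counts
#' @param x An `mb_ledger`.
#' @param ... Unused.
#' @return Tibble `category`, `n`, `percent`.
#' @export
tidy.mb_ledger <- function(x, ...) x$counts
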