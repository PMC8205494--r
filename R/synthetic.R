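# Synthetic-study generator: a tree with designated charge-shift clades,
# myoglobin-like sequences evolved under an empirical model with targeted
# charge-increasing substitutions on those clades, lifestyle labels drawn
# from a correlated liability, and a mobility panel — all with a complete
# truth log so every downstream stage can be scored offline.

#' A composite eulipotyphlan example phylogeny with lifestyle codes
#'
#' A synthetic, genus-level composite of the eulipotyphlan species tree
#' (solenodons, hedgehogs, shrews, moles) reproducing the clade structure
#' relevant to lifestyle evolution: five independently semi-aquatic lineages
#' (desmans, the star-nosed mole, the American water shrew, *Neomys*, and
#' *Chimarrogale* + *Nectogale*, the latter two separated by terrestrial
#' *Episoriculus* lineages) and two independently fossorial mole clades
#' (Talpini, Scalopini). Branch lengths are invented (Grafen method, scaled
#' to a 75-unit root depth, time-like); topology, not dates, is what the
#' parsimony analyses consume.
#'
#' @return List: `tree` (ultrametric `phylo`, 55 tips), `traits` (tibble
#'   `tip_id`, `lifestyle` over terrestrial/semi_fossorial/fossorial/
#'   semi_aquatic).
#' @export
example_eulipotyphla <- function() {
  erinaceidae <- paste0(
    "((Erinaceus_europaeus,Erinaceus_amurensis),",
    "(Hemiechinus_auritus,Atelerix_albiventris)),",
    "(Neotetracus_sinensis,Hylomys_suillus)")
  nectogalini <- paste0(
    "Neomys_fodiens,(Episoriculus_macrurus,((Chodsigoa_hypsibia,",
    "Episoriculus_caudatus),(Episoriculus_leucops,(Episoriculus_fumidus,",
    "(Chimarrogale_himalayica,Nectogale_elegans)))))")
  soricidae <- paste0(
    "(((Crocidura_russula,Crocidura_suaveolens),Crocidura_horsfieldii),",
    "(Suncus_murinus,Suncus_etruscus)),",
    "(((Blarina_brevicauda,Blarinella_quadraticauda),Anourosorex_squamipes),",
    "(((Sorex_araneus,Sorex_minutus),((Sorex_palustris,Sorex_monticolus),",
    "(Sorex_cinereus,Sorex_fumeus))),(", nectogalini, ")))")
  scalopini <- paste0(
    "Scapanulus_oweni,(Parascalops_breweri,(Scalopus_aquaticus,",
    "(Scapanus_townsendii,(Scapanus_latimanus,Scapanus_orarius))))")
  talpini <- paste0(
    "((Talpa_europaea,Talpa_romana),(Talpa_altaica,Talpa_occidentalis)),",
    "((Euroscaptor_malayana,(Euroscaptor_klossi,Euroscaptor_grandis)),",
    "(Mogera_wogura,(Mogera_imaizumii,(Mogera_insularis,Mogera_robusta))))")
  talpidae <- paste0(
    "(Uropsilus_gracilis,Uropsilus_soricipes),",
    "((Desmana_moschata,Galemys_pyrenaicus),",
    "((Scaptonyx_fusicaudus,(Urotrichus_talpoides,Dymecodon_pilirostris)),",
    "((Neurotrichus_gibbsii,(", scalopini, ")),",
    "(Condylura_cristata,(", talpini, ")))))")
  nwk <- paste0("(Solenodon_paradoxus,((", erinaceidae, "),((", soricidae,
                "),(", talpidae, "))));")
  tr <- ape::read.tree(text = nwk)
  tr <- ape::compute.brlen(tr, method = "Grafen", power = 1)
  tr$edge.length <- tr$edge.length * 75
  tr <- prepare_tree(tr)
  semi_aquatic <- c("Desmana_moschata", "Galemys_pyrenaicus", "Condylura_cristata",
                    "Sorex_palustris", "Neomys_fodiens",
                    "Chimarrogale_himalayica", "Nectogale_elegans")
  fossorial <- c("Parascalops_breweri", "Scalopus_aquaticus", "Scapanus_latimanus",
                 "Scapanus_orarius", "Scapanus_townsendii", "Scapanulus_oweni",
                 "Talpa_europaea", "Talpa_romana", "Talpa_altaica",
                 "Talpa_occidentalis", "Euroscaptor_malayana",
                 "Euroscaptor_klossi", "Euroscaptor_grandis",
                 "Mogera_wogura", "Mogera_imaizumii", "Mogera_insularis",
                 "Mogera_robusta")
  semi_fossorial <- c("Uropsilus_gracilis", "Uropsilus_soricipes",
                      "Scaptonyx_fusicaudus", "Urotrichus_talpoides",
                      "Dymecodon_pilirostris", "Neurotrichus_gibbsii",
                      "Blarina_brevicauda", "Blarinella_quadraticauda",
                      "Anourosorex_squamipes")
  lifestyle <- dplyr::case_when(
    tr$tip.label %in% semi_aquatic ~ "semi_aquatic",
    tr$tip.label %in% fossorial ~ "fossorial",
    tr$tip.label %in% semi_fossorial ~ "semi_fossorial",
    TRUE ~ "terrestrial")
  list(tree = tr, traits = tibble(tip_id = tr$tip.label, lifestyle = lifestyle))
}

#' Deterministic myoglobin-like root sequence
#'
#' A 153-residue sequence drawn once (fixed internal RNG stream) from the
#' Dayhoff stationary distribution and then adjusted to a myoglobin-like
#' ionizable composition (about 19 ionizable side chains, roughly balanced
#' acids and bases, no Cys). The same string is returned on every call;
#' supply a real myoglobin sequence to override it in a [scenario()].
#'
#' @param length Number of residues (default 153).
#' @return Protein string.
#' @export
default_root_sequence <- function(length = 153) {
  model <- substitution_model("Dayhoff")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(193L)
  res <- sample(AA_SYMBOLS, length, replace = TRUE, prob = model$pi)
  res[res == "C"] <- "A"
  # trim ionizables to ~19 with a near-neutral net charge at pH 6.5,
  # the regime of extant terrestrial myoglobins
  target <- c(D = 5, E = 4, K = 6, R = 2, H = 2)
  for (a in names(target)) {
    pos <- which(res == a)
    if (length(pos) > target[[a]]) {
      res[sample(pos, length(pos) - target[[a]])] <- "G"
    } else if (length(pos) < target[[a]]) {
      neutral <- which(!res %in% c("D", "E", "K", "R", "H"))
      res[sample(neutral, target[[a]] - length(pos))] <- a
    }
  }
  paste(res, collapse = "")
}

#' Define a synthetic study scenario
#'
#' @param tree A rooted `phylo` (default: the composite example tree).
#' @param root_seq Root protein sequence (default
#'   [default_root_sequence()]).
#' @param rho Background substitution rate per site per branch-length unit
#'   (default 0.002, giving paper-like divergence over a 75-unit-deep tree).
#' @param alpha Discrete-gamma shape for among-site rates (default 0.8).
#' @param K Gamma categories (default 4).
#' @param shift_branches Tibble `child_id`, `target_dzmb`: branches that
#'   receive targeted charge-increasing substitutions. Default: the stems of
#'   the five semi-aquatic clades of the example tree, each with target +2
#'   (the regime where semi-aquatic lineages stand ~2 charge units above
#'   background).
#' @param r_true Liability correlation used for lifestyle labels (default
#'   0.8).
#' @param charge_purify Probability that a background substitution altering
#'   the side-chain charge by 0.5 e or more is rejected (default 0.8),
#'   emulating the purifying selection that keeps real myoglobin surface
#'   charge nearly constant outside adaptive shifts; 0 gives the neutral
#'   process.
#' @param mobility_slope,mobility_intercept,mobility_noise_sd Mobility-panel
#'   generator coefficients (defaults 0.1488, 0.3075, 0.02).
#' @param seed Mandatory RNG seed.
#' @return A `scenario` list, validated.
#' @export
scenario <- function(tree = NULL, root_seq = NULL, rho = 0.002, alpha = 0.8,
                     K = 4, shift_branches = NULL, r_true = 0.8,
                     charge_purify = 0.8,
                     mobility_slope = 0.1488, mobility_intercept = 0.3075,
                     mobility_noise_sd = 0.02, seed) {
  if (missing(seed)) abort("scenario requires an explicit seed")
  if (is.null(tree)) tree <- example_eulipotyphla()$tree
  tree <- prepare_tree(tree)
  if (is.null(root_seq)) root_seq <- default_root_sequence()
  if (is.null(shift_branches)) {
    idx <- tree_index(tree)
    mrca_id <- function(tips) {
      tips <- intersect(tips, tree$tip.label)
      if (length(tips) == 0) return(NULL)
      if (length(tips) == 1) return(tips)
      idx$ids[ape::getMRCA(tree, tips)]
    }
    stems <- c(mrca_id(c("Desmana_moschata", "Galemys_pyrenaicus")),
               mrca_id("Condylura_cristata"),
               mrca_id("Sorex_palustris"),
               mrca_id("Neomys_fodiens"),
               mrca_id(c("Chimarrogale_himalayica", "Nectogale_elegans")))
    stems <- stems[!is.null(stems)]
    shift_branches <- tibble(child_id = unlist(stems), target_dzmb = 2)
  }
  missing_nodes <- setdiff(shift_branches$child_id, node_ids(tree))
  if (length(missing_nodes) > 0) {
    abort(paste0("shift branch child not in tree: ", paste(missing_nodes, collapse = ", ")))
  }
  if (abs(r_true) >= 1) abort("r_true must lie in (-1, 1)")
  if (charge_purify < 0 || charge_purify > 1) abort("charge_purify must lie in [0, 1]")
  out <- list(tree = tree, root_seq = root_seq, rho = rho, alpha = alpha,
              K = as.integer(K), shift_branches = shift_branches,
              r_true = r_true, charge_purify = charge_purify,
              mobility_slope = mobility_slope,
              mobility_intercept = mobility_intercept,
              mobility_noise_sd = mobility_noise_sd, seed = as.integer(seed))
  class(out) <- "mb_scenario"
  out
}

#' Simulate sequence evolution with planted charge shifts
#'
#' Sequences evolve site-independently along the tree under the empirical
#' model with discrete-gamma site rates (transition matrices by matrix
#' exponentiation per branch). On each designated charge-shift branch,
#' targeted substitutions (neutral residue -> Lys/Arg, or Asp/Glu -> Asn/Gln)
#' are applied at randomly chosen eligible sites after background evolution
#' until the branch's Z_Mb increment reaches its target. Every substitution
#' — background and planted — is logged.
#'
#' @param sc A [scenario()].
#' @param model `mb_submodel` (default Dayhoff).
#' @param ph pH used to evaluate the planted-shift targets (default 6.5).
#' @return List: `tips` (alignment tibble), `ancestors` (alignment tibble of
#'   internal nodes, truth), `truth_log` (tibble `parent_id`, `child_id`,
#'   `site`, `from_res`, `to_res`, `planted`), `site_rates`, `scenario`.
#' @export
simulate_alignment <- function(sc, model = substitution_model("Dayhoff"),
                               ph = 6.5) {
  stopifnot(inherits(sc, "mb_scenario"))
  set.seed(sc$seed)
  idx <- tree_index(sc$tree)
  S <- nchar(sc$root_seq)
  rates <- discrete_gamma_rates(sc$alpha, sc$K)
  site_cat <- sample.int(rates$K, S, replace = TRUE)
  site_rate <- rates$rates[site_cat]

  n_all <- idx$ntip + idx$nnode
  seqs <- vector("list", n_all)
  seqs[[idx$root]] <- match(strsplit(sc$root_seq, "")[[1]], AA_SYMBOLS)
  if (anyNA(seqs[[idx$root]])) abort("root sequence contains non-standard residues")
  lut <- residue_charges(ph)[AA_SYMBOLS]
  log_rows <- list()
  targets <- stats::setNames(sc$shift_branches$target_dzmb, sc$shift_branches$child_id)

  preorder_edges <- rev(seq_len(nrow(idx$edge)))
  for (i in preorder_edges) {
    p <- idx$edge[i, 1]; ch <- idx$edge[i, 2]
    t_e <- idx$blen[ch] * sc$rho
    parent_seq <- seqs[[p]]
    child_seq <- integer(S)
    for (k in unique(site_cat)) {
      sel <- which(site_cat == k)
      P <- prob_matrix(model, t_e * rates$rates[k])
      for (s in sel) {
        cand <- sample.int(20, 1, prob = P[parent_seq[s], ])
        # purifying filter on background charge changes
        if (cand != parent_seq[s] &&
            abs(lut[cand] - lut[parent_seq[s]]) >= 0.5 &&
            stats::runif(1) < sc$charge_purify) {
          cand <- parent_seq[s]
        }
        child_seq[s] <- cand
      }
    }
    ch_id <- idx$ids[ch]
    if (ch_id %in% names(targets)) {
      dz <- sum(lut[child_seq]) - sum(lut[parent_seq])
      while (dz < targets[[ch_id]] - 1e-9) {
        gain_sites <- which(abs(lut[child_seq]) < 0.5 &
                              !AA_SYMBOLS[child_seq] %in% c("K", "R"))
        loss_sites <- which(AA_SYMBOLS[child_seq] %in% c("D", "E"))
        cand <- c(gain_sites, loss_sites)
        if (length(cand) == 0) abort(paste0("charge-shift target unreachable on ", ch_id))
        s <- cand[sample.int(length(cand), 1)]
        old <- child_seq[s]
        new_res <- if (s %in% gain_sites) sample(c("K", "R"), 1) else
          c(D = "N", E = "Q")[[AA_SYMBOLS[old]]]
        child_seq[s] <- match(new_res, AA_SYMBOLS)
        dz <- dz + lut[child_seq[s]] - lut[old]
        log_rows[[length(log_rows) + 1]] <- tibble(
          parent_id = idx$ids[p], child_id = ch_id, site = s,
          from_res = AA_SYMBOLS[old], to_res = new_res, planted = TRUE)
      }
    }
    diff <- which(child_seq != parent_seq)
    planted <- if (length(log_rows)) {
      done <- dplyr::bind_rows(log_rows)
      diff_planted <- done$site[done$child_id == ch_id & done$planted]
      diff <- setdiff(diff, diff_planted)
      diff
    } else diff
    if (length(planted) > 0) {
      log_rows[[length(log_rows) + 1]] <- tibble(
        parent_id = idx$ids[p], child_id = ch_id, site = planted,
        from_res = AA_SYMBOLS[parent_seq[planted]],
        to_res = AA_SYMBOLS[child_seq[planted]], planted = FALSE)
    }
    seqs[[ch]] <- child_seq
  }
  to_string <- function(v) paste(AA_SYMBOLS[v], collapse = "")
  tips <- new_alignment(tibble(
    id = idx$tree$tip.label,
    seq = vapply(seq_len(idx$ntip), function(i) to_string(seqs[[i]]), character(1))))
  anc <- new_alignment(tibble(
    id = idx$ids[(idx$ntip + 1L):n_all],
    seq = vapply((idx$ntip + 1L):n_all, function(i) to_string(seqs[[i]]), character(1))))
  truth <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble(parent_id = character(), child_id = character(), site = integer(),
           from_res = character(), to_res = character(), planted = logical())
  list(tips = tips, ancestors = anc, truth_log = truth,
       site_rates = site_rate, scenario = sc)
}

#' Simulate a binary lifestyle from a liability correlated with Z_Mb
#'
#' The liability is `r_true` times the standardised Z_Mb plus
#' `sqrt(1 - r_true^2)` times an independent Brownian deviate on the tree
#' (unit variance at the tips); the state is the sign of the liability. With
#' `r_true = 1` and the default centring at the Z_Mb median, the labels
#' exactly partition the tips by Z_Mb.
#'
#' @param tr Rooted tree.
#' @param zmb_values Named numeric (tip -> Z_Mb) or tibble `tip_id`, `zmb`.
#' @param r_true Correlation in (-1, 1] (1 allowed: deterministic limit).
#' @param seed RNG seed.
#' @param center Liability zero point on the Z_Mb scale (default
#'   `median(zmb)`).
#' @return Tibble `tip_id`, `state`, `liability`.
#' @export
simulate_binary_trait <- function(tr, zmb_values, r_true, seed, center = NULL) {
  tr <- prepare_tree(tr)
  if (is.data.frame(zmb_values)) {
    zmb_values <- stats::setNames(zmb_values$zmb, zmb_values$tip_id)
  }
  z <- zmb_values[tr$tip.label]
  if (anyNA(z)) abort("zmb_values must cover every tip")
  if (abs(r_true) > 1) abort("r_true must lie in [-1, 1]")
  set.seed(seed)
  if (is.null(center)) center <- stats::median(z)
  zs <- (z - center) / max(stats::sd(z), 1e-12)
  e <- brownian_deviates(tr)
  liab <- r_true * zs + sqrt(max(0, 1 - r_true^2)) * e
  tibble(tip_id = tr$tip.label, state = as.integer(liab > 0),
         liability = unname(liab))
}

# one multivariate-normal draw with tree covariance scaled to unit average
# tip variance
brownian_deviates <- function(tr) {
  C <- ape::vcv(tr)
  C <- C / mean(diag(C))
  L <- chol(C)
  as.numeric(t(L) %*% stats::rnorm(nrow(C)))
}

#' Simulate an electrophoretic-mobility panel from Z_Mb
#'
#' `y = slope * Z_Mb + intercept + noise`, the noise Brownian-structured on
#' the tree with tip standard deviation `noise_sd`.
#'
#' @param tr Rooted tree.
#' @param zmb_values Named numeric or tibble `tip_id`, `zmb`.
#' @param slope,intercept Generator coefficients (defaults 0.1488, 0.3075,
#'   the reference calibration of relative mobility against net charge).
#' @param noise_sd Tip noise SD (>= 0; 0 = exact line).
#' @param seed RNG seed.
#' @return Tibble `tip_id`, `zmb`, `mobility`.
#' @export
simulate_mobility <- function(tr, zmb_values, slope = 0.1488,
                              intercept = 0.3075, noise_sd = 0.02, seed = 1) {
  tr <- prepare_tree(tr)
  if (is.data.frame(zmb_values)) {
    zmb_values <- stats::setNames(zmb_values$zmb, zmb_values$tip_id)
  }
  z <- zmb_values[tr$tip.label]
  if (anyNA(z)) abort("zmb_values must cover every tip")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  set.seed(seed)
  eps <- if (noise_sd > 0) noise_sd * brownian_deviates(tr) else 0
  tibble(tip_id = tr$tip.label, zmb = unname(z),
         mobility = unname(slope * z + intercept + eps))
}

#' Simulate a full synthetic study
#'
#' Runs [simulate_alignment()], computes tip Z_Mb, draws lifestyle labels
#' ([simulate_binary_trait()]) and a mobility panel ([simulate_mobility()]),
#' all under the scenario's seed (sub-streams derived deterministically).
#'
#' @param sc A [scenario()].
#' @param ph pH (default 6.5).
#' @return List: `alignment` (tips), `ancestors`, `truth_log`, `zmb`
#'   (tibble), `traits` (tibble `tip_id`, `state`, `liability`), `mobility`,
#'   `tree`, `scenario`.
#' @export
simulate_study <- function(sc, ph = 6.5) {
  sim <- simulate_alignment(sc, ph = ph)
  z <- zmb(sim$tips, ph = ph)
  ztab <- tibble(tip_id = z$id, zmb = z$zmb)
  traits <- simulate_binary_trait(sc$tree, ztab, sc$r_true, seed = sc$seed + 1L)
  mob <- simulate_mobility(sc$tree, ztab, sc$mobility_slope,
                           sc$mobility_intercept, sc$mobility_noise_sd,
                           seed = sc$seed + 2L)
  list(alignment = sim$tips, ancestors = sim$ancestors,
       truth_log = sim$truth_log, zmb = ztab, traits = traits,
       lifestyle_truth = shifted_clade_trait(sc),
       mobility = mob, tree = sc$tree, scenario = sc)
}

#' Ground-truth derived-lifestyle labels of a scenario
#'
#' The scenario's designated charge-shift branches define its "true"
#' derived-lifestyle clades (as in the study design, where lifestyle is an
#' observed character aligned with the charge-shifted lineages): every tip
#' descending from a shift branch is state 1.
#'
#' @param sc A [scenario()].
#' @return Tibble `tip_id`, `state`.
#' @export
shifted_clade_trait <- function(sc) {
  idx <- tree_index(sc$tree)
  shifted <- unique(unlist(lapply(sc$shift_branches$child_id, function(id) {
    nd <- match(id, idx$ids)
    if (nd <= idx$ntip) return(idx$ids[nd])
    ape::extract.clade(sc$tree, nd)$tip.label
  })))
  tibble(tip_id = sc$tree$tip.label,
         state = as.integer(sc$tree$tip.label %in% shifted))
}
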