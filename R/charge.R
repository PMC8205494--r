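#' Default ionizable-group pKa table
#'
#' One row per ionizable side chain plus the two peptide termini. Acidic
#' groups (Asp, Glu, Cys, Tyr, C-terminus) carry fractional charge
#' \eqn{-1/(1+10^{pKa-pH})}; basic groups (His, Lys, Arg, N-terminus) carry
#' \eqn{+1/(1+10^{pH-pKa})}. Values are conventional free-residue constants;
#' the whole table, or individual sites, can be overridden (see
#' [read_pka_table()] and the `site_pka` argument of [net_charge()]).
#'
#' @return Tibble with columns `group`, `polarity` (`"acid"`/`"base"`),
#'   `pka`.
#' @export
default_pka_table <- function() {
  tibble(
    group    = c("D", "E", "H", "C", "Y", "K", "R", "nterm", "cterm"),
    polarity = c("acid", "acid", "base", "acid", "acid", "base", "base",
                 "base", "acid"),
    pka      = c(3.90, 4.25, 6.50, 8.50, 10.46, 10.53, 12.48, 8.00, 3.60)
  )
}

#' Read a pKa table from TSV
#'
#' Columns `group`, `polarity`, `pka`. Rows whose `group` is a 1-based site
#' index (all digits) are per-site overrides and are returned in the
#' `site_pka` attribute as a tibble `site`, `polarity`, `pka`.
#'
#' @param path TSV file.
#' @return pKa tibble (residue/termini rows), with attribute `site_pka`.
#' @export
read_pka_table <- function(path) {
  x <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("group", "polarity", "pka") %in% names(x))) {
    abort("pKa table must have columns group, polarity, pka")
  }
  validate_pka(x)
  is_site <- grepl("^[0-9]+$", x$group)
  tab <- x[!is_site, ]
  ov <- x[is_site, ]
  attr(tab, "site_pka") <- tibble(site = as.integer(ov$group),
                                  polarity = ov$polarity, pka = ov$pka)
  tab
}

validate_pka <- function(tab) {
  if (any(tab$pka <= 0 | tab$pka >= 14)) abort("pKa values must lie in (0, 14)")
  if (!all(tab$polarity %in% c("acid", "base"))) {
    abort("polarity must be 'acid' or 'base'")
  }
  invisible(tab)
}

#' Fractional charge of one ionizable group at a given pH
#'
#' Henderson-Hasselbalch fractional ionization in elementary-charge units:
#' an acid contributes \eqn{-1/(1+10^{pKa-pH})} (in (-1,0)), a base
#' \eqn{+1/(1+10^{pH-pKa})} (in (0,1)). At `pH == pka` the magnitude is
#' exactly 0.5.
#'
#' @param polarity `"acid"` or `"base"` (vectorised).
#' @param pka Ionization constant(s), in (0, 14).
#' @param ph Solution pH, in (0, 14).
#' @return Fractional charge(s).
#' @export
group_charge <- function(polarity, pka, ph) {
  if (any(pka <= 0 | pka >= 14) || any(ph <= 0 | ph >= 14)) {
    abort("pKa and pH must lie in (0, 14)")
  }
  ifelse(polarity == "acid",
         -1 / (1 + 10^(pka - ph)),
         +1 / (1 + 10^(ph - pka)))
}

# per-residue side-chain charge lookup for one pH/table; named vector over
# the 20 residues plus '-' and 'X' (both 0)
residue_charges <- function(ph, pka_table = default_pka_table()) {
  validate_pka(pka_table)
  side <- pka_table[!pka_table$group %in% c("nterm", "cterm"), ]
  z <- stats::setNames(rep(0, 22), c(AA_SYMBOLS, "-", "X"))
  z[side$group] <- group_charge(side$polarity, side$pka, ph)
  z
}

terminus_charge <- function(which, ph, pka_table = default_pka_table()) {
  row <- pka_table[pka_table$group == which, ]
  if (nrow(row) != 1) abort(paste0("pKa table lacks a ", which, " row"))
  group_charge(row$polarity, row$pka, ph)
}

#' Net surface charge of a protein sequence (Z_Mb)
#'
#' Sums the Henderson-Hasselbalch fractional charge of every ionizable group
#' at the given pH. Gaps (`-`) and unknown residues (`X`) contribute zero.
#' Terminal amino/carboxyl contributions are added once when
#' `include_termini` is set. Full precision is retained; round with
#' [round_zmb()] for reporting (the field reports 2 decimals).
#'
#' @param seq Protein string over the amino-acid alphabet plus `-`/`X`, or a
#'   character vector of single residues.
#' @param ph Solution pH (default 6.5, the reference condition for
#'   myoglobin charge modelling).
#' @param pka_table pKa tibble (see [default_pka_table()]).
#' @param include_termini Add N-/C-terminus charges (default TRUE).
#' @param site_pka Optional per-site overrides: tibble `site`, `polarity`,
#'   `pka` in 1-based mature-peptide coordinates.
#' @return Tibble with one row per site: `site`, `residue`, `charge`;
#'   attributes `zmb` (total), `ph`, `termini` (named length-2 vector or
#'   NULL).
#' @export
net_charge <- function(seq, ph = 6.5, pka_table = default_pka_table(),
                       include_termini = TRUE, site_pka = NULL) {
  res <- if (length(seq) == 1 && nchar(seq[1]) > 1) strsplit(seq, "")[[1]] else seq
  lut <- residue_charges(ph, pka_table)
  unknown <- setdiff(res, names(lut))
  if (length(unknown) > 0) {
    abort(paste0("unknown residue symbol(s): ", paste(unknown, collapse = " ")))
  }
  charge <- unname(lut[res])
  if (!is.null(site_pka) && nrow(site_pka) > 0) {
    for (i in seq_len(nrow(site_pka))) {
      s <- site_pka$site[i]
      if (s <= length(res) && !res[s] %in% c("-", "X")) {
        charge[s] <- group_charge(site_pka$polarity[i], site_pka$pka[i], ph)
      }
    }
  }
  out <- tibble(site = seq_along(res), residue = res, charge = charge)
  total <- sum(charge)
  term <- NULL
  if (include_termini) {
    term <- c(nterm = terminus_charge("nterm", ph, pka_table),
              cterm = terminus_charge("cterm", ph, pka_table))
    total <- total + sum(term)
  }
  attr(out, "zmb") <- total
  attr(out, "ph") <- ph
  attr(out, "termini") <- term
  class(out) <- c("mb_charge_profile", class(out))
  out
}

#' Total Z_Mb of one or more sequences
#'
#' Convenience wrapper over [net_charge()] returning just the totals.
#'
#' @param aln Alignment tibble (`id`, `seq`) or a character vector of
#'   sequences.
#' @inheritParams net_charge
#' @return Tibble `id`, `zmb` (full precision), `zmb_2dp` (reporting
#'   precision, round-half-even).
#' @export
zmb <- function(aln, ph = 6.5, pka_table = default_pka_table(),
                include_termini = TRUE, site_pka = NULL) {
  if (is.character(aln)) {
    aln <- tibble(id = if (is.null(names(aln))) paste0("seq", seq_along(aln)) else names(aln),
                  seq = unname(aln))
  }
  vals <- vapply(aln$seq, function(s) {
    attr(net_charge(s, ph, pka_table, include_termini, site_pka), "zmb")
  }, numeric(1))
  tibble(id = aln$id, zmb = unname(vals), zmb_2dp = round_zmb(unname(vals)))
}

#' Round a charge to reporting precision (2 decimals, round-half-even)
#' @param x Numeric.
#' @return `x` rounded to 2 decimals.
#' @export
round_zmb <- function(x) round(x, 2)

#' Charge change of an amino-acid substitution
#'
#' Returns the side-chain fractional-charge difference `charge(to) -
#' charge(from)` at the given pH. Accepts one-letter or three-letter residue
#' codes. A substitution to or from a gap is an indel, not a substitution;
#' use the `delta` convention of [branch_substitutions()] for those.
#'
#' @param from_res,to_res Residues (e.g. `"S"`, `"Lys"`).
#' @param ph Solution pH.
#' @param pka_table pKa tibble.
#' @param site Optional 1-based site index, used with `site_pka`.
#' @param site_pka Optional per-site overrides (see [net_charge()]).
#' @return Numeric charge difference in elementary-charge units.
#' @export
substitution_delta <- function(from_res, to_res, ph = 6.5,
                               pka_table = default_pka_table(),
                               site = NULL, site_pka = NULL) {
  from_res <- aa1(from_res); to_res <- aa1(to_res)
  lut <- residue_charges(ph, pka_table)
  if (!is.null(site) && !is.null(site_pka)) {
    hit <- site_pka[site_pka$site == site, ]
    if (nrow(hit) == 1) {
      ov <- group_charge(hit$polarity, hit$pka, ph)
      get1 <- function(r) if (r %in% c("-", "X")) 0 else ov
      return(get1(to_res) - get1(from_res))
    }
  }
  unname(lut[to_res] - lut[from_res])
}

AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
         Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
         Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
         Tyr = "Y", Val = "V")

aa1 <- function(r) {
  if (nchar(r) == 3) {
    key <- paste0(toupper(substr(r, 1, 1)), tolower(substr(r, 2, 3)))
    if (!key %in% names(AA3)) abort(paste0("unknown residue code: ", r))
    return(unname(AA3[key]))
  }
  toupper(r)
}

#' Classify a charge change as increasing, decreasing or neutral
#'
#' A substitution is charge-increasing when its delta meets the threshold
#' (default 0.5 elementary charges, so a full Asp/Glu loss or Lys/Arg gain at
#' pH 6.5 — each ~ +1 — classifies as increasing, while His protonation
#' shifts near 0.5 split at the boundary).
#'
#' @param delta Numeric charge change(s).
#' @param threshold Positive classification threshold (default 0.5).
#' @return Character vector over `"increasing"`, `"decreasing"`, `"neutral"`.
#' @export
classify_charge_change <- function(delta, threshold = 0.5) {
  if (threshold <= 0) abort("threshold must be positive")
  ifelse(delta >= threshold, "increasing",
         ifelse(delta <= -threshold, "decreasing", "neutral"))
}

#' @export
print.mb_charge_profile <- function(x, ...) {
  cat(sprintf("Per-site charge profile: %d sites, pH %.2f, Z = %.2f\n",
              nrow(x), attr(x, "ph"), attr(x, "zmb")))
  NextMethod()
}

#' Per-site charge profile plot
#'
#' @param object A charge profile from [net_charge()].
#' @param ... Unused.
#' @return A ggplot: per-site fractional charge vs mature position.
#' @export
autoplot.mb_charge_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[df$charge != 0, ],
                  ggplot2::aes(x = .data$site, y = .data$charge)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$site, yend = 0,
                                       colour = .data$charge > 0)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
                                 labels = c(`TRUE` = "basic", `FALSE` = "acidic"),
                                 name = NULL) +
    ggplot2::labs(x = "mature-peptide position", y = "fractional charge (e)",
                  title = sprintf("Net charge %.2f at pH %.2f",
                                  attr(object, "zmb"), attr(object, "ph"))) +
    ggplot2::theme_minimal()
}
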