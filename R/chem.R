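# Protonation-state bookkeeping (Henderson-Hasselbalch, independent sites),
# strong acid/base mixing, and DFT frequency-scaling utilities.

#' Ionizable group
#'
#' @param name Group label.
#' @param pka Acid dissociation constant (0 < pKa < 14 unless blocked).
#' @param type `"base"` (+1 when protonated, 0 otherwise) or `"acid"`
#'   (0 when protonated, -1 otherwise).
#' @param blocked Chemically blocked group (amidated C-terminus,
#'   disulfide-bonded cysteine thiol): contributes zero charge at all pH.
#' @export
ionizable_group <- function(name, pka, type = c("base", "acid"),
                            blocked = FALSE) {
  type <- match.arg(type)
  if (!blocked && (is.na(pka) || pka <= 0 || pka >= 14))
    stop("pKa of unblocked group \"", name,
         "\" must lie strictly inside (0, 14)")
  structure(list(name = name, pka = pka, type = type, blocked = blocked),
            class = "ionizable_group")
}

#' Default hIAPP ionizable-group set
#'
#' Amylin has four basic sites (N-terminal alpha-amino, Lys-1, Arg-11 and
#' His-18 with pKa 6.0), an amidated C-terminus and both cysteines tied in
#' the Cys2-Cys7 disulfide, and no acidic side chains: all non-basic groups
#' are blocked. Only the His pKa is peptide-specific; the others are the
#' standard free-residue values and are configurable.
#'
#' @param pka_his,pka_nterm,pka_lys,pka_arg Site pKa values.
#' @export
hiapp_groups <- function(pka_his = 6.0, pka_nterm = 9.0, pka_lys = 10.5,
                         pka_arg = 12.5) {
  list(ionizable_group("alpha_amino", pka_nterm, "base"),
       ionizable_group("Lys1", pka_lys, "base"),
       ionizable_group("Arg11", pka_arg, "base"),
       ionizable_group("His18", pka_his, "base"),
       ionizable_group("C_term_amide", NA, "acid", blocked = TRUE),
       ionizable_group("Cys2", NA, "acid", blocked = TRUE),
       ionizable_group("Cys7", NA, "acid", blocked = TRUE))
}

#' Free tyrosine ionizable groups
#' @param pka_carboxyl,pka_amino,pka_phenol Site pKa values.
#' @export
tyr_groups <- function(pka_carboxyl = 2.2, pka_amino = 9.2,
                       pka_phenol = 10.5) {
  list(ionizable_group("carboxyl", pka_carboxyl, "acid"),
       ionizable_group("amino", pka_amino, "base"),
       ionizable_group("phenol", pka_phenol, "acid"))
}

site_protonated_fraction <- function(group, pH)
  if (group$blocked) NA_real_ else 1 / (1 + 10^(pH - group$pka))

site_charge <- function(group, f) {
  if (group$blocked) return(0)
  if (group$type == "base") f else -(1 - f)
}

#' Net charge at a given pH
#'
#' Per-site protonated fraction `f = 1 / (1 + 10^(pH - pKa))`; a base
#' contributes `+f`, an acid `-(1 - f)`, a blocked group 0. The integer
#' charge is the rounded fractional sum. Monotone non-increasing in pH.
#'
#' @param groups List of [ionizable_group()]s (non-empty).
#' @param pH Solution pH in \[0, 14\].
#' @return Object of class `charge_state`: `fractional_charge`,
#'   `integer_charge`, `site_fractions`.
#' @export
net_charge <- function(groups, pH) {
  if (length(groups) == 0) stop("empty ionizable group list")
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]")
  f <- vapply(groups, site_protonated_fraction, numeric(1), pH = pH)
  q <- sum(mapply(site_charge, groups, f))
  names(f) <- vapply(groups, `[[`, "", "name")
  structure(list(fractional_charge = q, integer_charge = as.integer(round(q)),
                 site_fractions = f), class = "charge_state")
}

#' @export
print.charge_state <- function(x, ...) {
  cat(sprintf("<charge_state> %+d (fractional %+.3f)\n", x$integer_charge,
              x$fractional_charge))
  invisible(x)
}

#' Microstate weights aggregated by net charge
#'
#' Independent-sites model: every combination of protonated/deprotonated
#' unblocked sites has weight equal to the product of per-site Bernoulli
#' protonation probabilities; weights are aggregated by the microstate's
#' total charge. Weights sum to 1 at any pH, and the per-site marginals
#' equal the Henderson-Hasselbalch fractions of [net_charge()].
#'
#' @inheritParams net_charge
#' @return A `data.frame` with columns `charge` and `weight`, plus a
#'   `site_fractions` attribute.
#' @export
microstate_weights <- function(groups, pH) {
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]")
  free <- Filter(function(g) !g$blocked, groups)
  if (length(free) == 0)
    return(structure(data.frame(charge = 0, weight = 1),
                     site_fractions = numeric(0)))
  f <- vapply(free, site_protonated_fraction, numeric(1), pH = pH)
  k <- length(free)
  states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
  w <- apply(states, 1, function(prot) prod(ifelse(prot, f, 1 - f)))
  q <- apply(states, 1, function(prot)
    sum(mapply(function(g, p)
      if (g$type == "base") as.numeric(p) else -(1 - as.numeric(p)),
      free, prot)))
  agg <- stats::aggregate(list(weight = w), by = list(charge = q), FUN = sum)
  agg <- agg[order(agg$charge), ]
  rownames(agg) <- NULL
  names(f) <- vapply(free, `[[`, "", "name")
  structure(agg, site_fractions = f)
}

#' pH after mixing a strong acid with a strong base
#'
#' Ideal mixing of a strong monoprotic acid (concentration `10^-pH_acid`)
#' with NaOH, then the charge-balance solution including water
#' autoionization: `[H+] - Kw/[H+] = C_acid - C_base`, a quadratic with the
#' positive root `h = (d + sqrt(d^2 + 4 Kw)) / 2`. Strictly monotone
#' decreasing of `[H+]` in added base; recovers `pH_acid` at `v_base = 0`.
#'
#' @param v_acid Acid volume (uL), > 0.
#' @param pH_acid Initial acid pH.
#' @param v_base Added base volume (uL), >= 0.
#' @param c_base Base concentration (mol/L), > 0.
#' @param Kw Water autoionization constant (default 1e-14, 25 C).
#' @return The mixture pH.
#' @export
mix_strong_acid_base <- function(v_acid, pH_acid, v_base, c_base, Kw = 1e-14) {
  if (v_acid <= 0 || v_base < 0 || c_base <= 0)
    stop("volumes must be positive (v_base >= 0) and c_base > 0")
  c_acid <- 10^(-pH_acid)
  vt <- v_acid + v_base
  d <- (c_acid * v_acid - c_base * v_base) / vt
  h <- (d + sqrt(d^2 + 4 * Kw)) / 2
  -log10(h)
}

#' Apply an empirical frequency scaling factor
#'
#' Multiplies calculated vibrational wavenumbers above `cutoff` by `factor`
#' (default 0.9770 above 1000 cm^-1, the usual correction for systematic
#' overestimation of harmonic DFT frequencies in the high-wavenumber
#' region); wavenumbers at or below the cutoff are unchanged.
#'
#' @param freqs Positive wavenumbers (cm^-1).
#' @param factor Scaling factor, > 0.
#' @param cutoff Scaling applies strictly above this wavenumber.
#' @export
apply_freq_scaling <- function(freqs, factor = 0.9770, cutoff = 1000) {
  if (factor <= 0) stop("scaling factor must be > 0")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  ifelse(freqs > cutoff, freqs * factor, freqs)
}

#' Least-squares frequency scaling factor
#'
#' The factor minimizing `sum((obs - f * calc)^2)` over paired calculated
#' and observed wavenumbers: the regression through the origin
#' `f = sum(calc * obs) / sum(calc^2)`.
#'
#' @param calc Calculated wavenumbers (> 0).
#' @param obs Observed wavenumbers, same length.
#' @export
fit_scaling_factor <- function(calc, obs) {
  if (length(calc) == 0 || length(calc) != length(obs))
    stop("calc and obs must be non-empty paired vectors of equal length")
  if (any(calc <= 0)) stop("calculated frequencies must be positive")
  sum(calc * obs) / sum(calc^2)
}
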