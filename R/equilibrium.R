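# Sequential two-site metal-binding equilibrium.
#
# A peptide P with a high-affinity and a low-affinity Ag+ site binds
# stepwise: P + Ag <-> PAg (stepwise dissociation constant kd1) and
# PAg + Ag <-> PAg2 (kd2), with kd1 < kd2 in the systems studied here. The
# species concentrations at given totals follow from the two mass-balance
# laws; they reduce to a single monotone scalar equation in free Ag+, which
# is solved by a bracketed root find with a Newton polish.

#' Sequential two-site binding model
#'
#' @param kd1 Stepwise dissociation constant of the first (high-affinity)
#'   site, `[P][Ag]/[PAg]`, in uM.
#' @param kd2 Stepwise dissociation constant of the second site,
#'   `[PAg][Ag]/[PAg2]`, in uM.
#' @return Object of class `binding_model`.
#' @export
binding_model <- function(kd1, kd2) {
  stopifnot(is.numeric(kd1), kd1 > 0, is.numeric(kd2), kd2 > 0)
  structure(list(kd1 = kd1, kd2 = kd2), class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> KD1 = %.4g uM, KD2 = %.4g uM\n", x$kd1, x$kd2))
  invisible(x)
}

# bound Ag and peptide partition at free-Ag concentration a
.species_at_free_ag <- function(model, p_total, a) {
  k1 <- model$kd1
  k2 <- model$kd2
  denom <- 1 + a / k1 + a^2 / (k1 * k2)
  p_free <- p_total / denom
  pag <- p_free * a / k1
  pag2 <- pag * a / k2
  list(p_free = p_free, pag = pag, pag2 = pag2)
}

#' Solve species concentrations of the two-site equilibrium
#'
#' Finds the unique non-negative root of the coupled mass balances
#' `[PAg] = [P][Ag]/kd1`, `[PAg2] = [PAg][Ag]/kd2`,
#' `[P] + [PAg] + [PAg2] = p_total`, `[Ag] + [PAg] + 2[PAg2] = ag_total`
#' by a bracketed root find on free Ag in `[0, ag_total]` followed by
#' Newton refinement. Both conservation laws are verified to a relative
#' tolerance of 1e-9.
#'
#' @param model A [binding_model()].
#' @param p_total Total peptide concentration (uM, >= 0).
#' @param ag_total Total Ag+ concentration (uM, >= 0).
#' @return List of class `species_state` with `p_free`, `pag`, `pag2`,
#'   `ag_free`, `p_total`, `ag_total` (uM).
#' @export
solve_species <- function(model, p_total, ag_total) {
  stopifnot(inherits(model, "binding_model"),
            is.numeric(p_total), p_total >= 0,
            is.numeric(ag_total), ag_total >= 0)
  mk <- function(a) {
    s <- .species_at_free_ag(model, p_total, a)
    structure(
      list(p_free = s$p_free, pag = s$pag, pag2 = s$pag2, ag_free = a,
           p_total = p_total, ag_total = ag_total),
      class = "species_state"
    )
  }
  if (ag_total == 0 || p_total == 0) {
    out <- mk(ag_total)
    return(.check_balance(out))
  }
  g <- function(a) {
    s <- .species_at_free_ag(model, p_total, a)
    a + s$pag + 2 * s$pag2 - ag_total
  }
  root <- stats::uniroot(
    g, lower = 0, upper = ag_total,
    f.lower = -ag_total, f.upper = g(ag_total),
    tol = .Machine$double.eps^0.75 * max(1, ag_total), maxiter = 200
  )$root
  # Newton polish: g is smooth and strictly increasing on [0, ag_total]
  k1 <- model$kd1
  k2 <- model$kd2
  a <- root
  for (it in 1:8) {
    denom <- 1 + a / k1 + a^2 / (k1 * k2)
    p_free <- p_total / denom
    bound <- p_free * (a / k1 + 2 * a^2 / (k1 * k2))
    fa <- a + bound - ag_total
    dden <- 1 / k1 + 2 * a / (k1 * k2)
    dbound <- p_total * ((1 / k1 + 4 * a / (k1 * k2)) * denom -
                           (a / k1 + 2 * a^2 / (k1 * k2)) * dden) / denom^2
    step <- fa / (1 + dbound)
    a_new <- min(max(a - step, 0), ag_total)
    if (abs(a_new - a) <= 1e-15 * max(1, a)) {
      a <- a_new
      break
    }
    a <- a_new
  }
  .check_balance(mk(a))
}

.check_balance <- function(state) {
  p_sum <- state$p_free + state$pag + state$pag2
  ag_sum <- state$ag_free + state$pag + 2 * state$pag2
  tol_p <- 1e-9 * max(1, state$p_total)
  tol_a <- 1e-9 * max(1, state$ag_total)
  if (abs(p_sum - state$p_total) > tol_p ||
      abs(ag_sum - state$ag_total) > tol_a) {
    stop(sprintf(
      paste0("equilibrium solver failed to satisfy mass balance ",
             "(peptide residual %.3e, metal residual %.3e)"),
      p_sum - state$p_total, ag_sum - state$ag_total))
  }
  state
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf(
    "<species_state> P %.4g, PAg %.4g, PAg2 %.4g, free Ag %.4g uM (totals %g/%g)\n",
    x$p_free, x$pag, x$pag2, x$ag_free, x$p_total, x$ag_total))
  invisible(x)
}

#' Binding isotherm over a set of titration ratios
#'
#' Solves the two-site equilibrium at `ag_total = ratio * p_total` for each
#' ratio.
#'
#' @param model A [binding_model()].
#' @param p_total Total peptide concentration (uM).
#' @param ratios Numeric vector of Ag+:peptide ratios (>= 0).
#' @return data.frame with one row per ratio: `ratio`, `ag_total`,
#'   `p_free`, `pag`, `pag2`, `ag_free`, `mean_occupancy`.
#' @export
binding_isotherm <- function(model, p_total, ratios) {
  stopifnot(all(ratios >= 0))
  rows <- lapply(ratios, function(r) {
    s <- solve_species(model, p_total, r * p_total)
    data.frame(
      ratio = r, ag_total = r * p_total,
      p_free = s$p_free, pag = s$pag, pag2 = s$pag2, ag_free = s$ag_free,
      mean_occupancy = if (p_total > 0) (s$pag + 2 * s$pag2) / p_total else 0
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
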