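# ESI-MS species assignment and dissociation-constant fitting.
#
# Positive-mode metalated-peptide adduct convention: each bound Ag+ carries
# its own charge into the ion; the remaining charges are protons. So a
# k-mer with n bound silver ions at charge z has
#   m/z = (k*M + n*m(Ag+) + (z - n)*m(H+)) / z,  requiring z >= n.

#' Theoretical m/z of a peptide/silver adduct ion
#'
#' @param peptide_mass Neutral monomer mass M (Da), e.g. from
#'   [peptide_mass()].
#' @param oligomer_k Number of peptide units (1 = monomer, 2 = dimer).
#' @param n_ag Number of bound Ag+ ions (>= 0).
#' @param charge_z Positive charge state (>= 1, and >= `n_ag`).
#' @param mode Mass convention for the Ag+ cation, `"average"` default.
#' @return m/z in Th.
#' @export
theoretical_mz <- function(peptide_mass, oligomer_k = 1L, n_ag = 0L,
                           charge_z = 1L,
                           mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(oligomer_k >= 1L, n_ag >= 0L, charge_z >= 1L)
  if (charge_z < n_ag) {
    stop(sprintf("charge deficit: z = %d < n_ag = %d under the ",
                 charge_z, n_ag),
         "one-charge-per-silver adduct convention")
  }
  (oligomer_k * peptide_mass + n_ag * .MASS_AG_CATION[[mode]] +
      (charge_z - n_ag) * .MASS_PROTON) / charge_z
}

# all valid (k, n, z) species over the search ranges
.species_grid <- function(peptide_mass, n_max, z_range, k_range, mode) {
  grid <- expand.grid(oligomer_k = k_range, n_ag = 0:n_max,
                      charge_z = z_range)
  grid <- grid[grid$charge_z >= grid$n_ag, , drop = FALSE]
  grid$theo_mz <- mapply(
    theoretical_mz, oligomer_k = grid$oligomer_k, n_ag = grid$n_ag,
    charge_z = grid$charge_z,
    MoreArgs = list(peptide_mass = peptide_mass, mode = mode)
  )
  rownames(grid) <- NULL
  grid
}

#' Assign centroided ESI-MS peaks to peptide/silver species
#'
#' Each centroid is matched to the closest theoretical m/z (in ppm) over a
#' grid of (oligomer, Ag count, charge) species; matches beyond `tol_ppm`
#' are left unassigned. When a centroid is within tolerance of two species,
#' the smaller ppm error wins; an exact tie is flagged ambiguous and the
#' peak is excluded from quantification. All positive charge states in
#' `z_range` contribute to one species' total area.
#'
#' @param spectrum An [ms_spectrum()].
#' @param peptide A [peptide_sequence()], one-letter string, or neutral
#'   monomer mass in Da.
#' @param n_max Maximum Ag count searched (default 3).
#' @param z_range Integer vector of charge states searched (default 2:3).
#' @param k_range Oligomer sizes searched (default 1:2, monomer and dimer).
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @param mode Mass convention, `"average"` default.
#' @return List of class `species_assignments`: `species` (one row per
#'   matched (k, n, z) with `theo_mz`, `total_area`, `n_peaks`), `peak_map`
#'   (per-centroid assignment with `status` matched/unmatched/ambiguous),
#'   plus the spectrum totals.
#' @export
assign_species <- function(spectrum, peptide, n_max = 3L, z_range = 2:3,
                           k_range = 1:2, tol_ppm = 10,
                           mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "ms_spectrum"), tol_ppm > 0)
  if (is.character(peptide) || inherits(peptide, "peptide_sequence")) {
    m <- peptide_mass(peptide, mode = mode)
  } else {
    stopifnot(is.numeric(peptide), peptide > 0)
    m <- peptide
  }
  grid <- .species_grid(m, n_max, z_range, k_range, mode)
  pk <- spectrum$peaks
  npk <- nrow(pk)
  map <- data.frame(
    mz = pk$mz, area = pk$area,
    oligomer_k = NA_integer_, n_ag = NA_integer_, charge_z = NA_integer_,
    theo_mz = NA_real_, ppm_error = NA_real_,
    status = rep("unmatched", npk),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(npk)) {
    ppm <- abs(pk$mz[i] - grid$theo_mz) / grid$theo_mz * 1e6
    within <- which(ppm <= tol_ppm)
    if (length(within) == 0L) next
    best <- within[order(ppm[within])]
    if (length(best) > 1L && ppm[best[1]] == ppm[best[2]]) {
      map$status[i] <- "ambiguous"
      next
    }
    b <- best[1]
    map$oligomer_k[i] <- grid$oligomer_k[b]
    map$n_ag[i] <- grid$n_ag[b]
    map$charge_z[i] <- grid$charge_z[b]
    map$theo_mz[i] <- grid$theo_mz[b]
    map$ppm_error[i] <- ppm[b]
    map$status[i] <- "matched"
  }
  matched <- map[map$status == "matched", , drop = FALSE]
  if (nrow(matched) > 0L) {
    key <- paste(matched$oligomer_k, matched$n_ag, matched$charge_z)
    agg <- lapply(split(seq_len(nrow(matched)), key), function(ix) {
      r <- matched[ix[1], ]
      data.frame(
        oligomer_k = r$oligomer_k, n_ag = r$n_ag, charge_z = r$charge_z,
        theo_mz = r$theo_mz,
        total_area = sum(matched$area[ix]),
        n_peaks = length(ix)
      )
    })
    species <- do.call(rbind, agg)
    species <- species[order(species$oligomer_k, species$n_ag,
                             species$charge_z), , drop = FALSE]
    rownames(species) <- NULL
  } else {
    species <- data.frame(
      oligomer_k = integer(0), n_ag = integer(0), charge_z = integer(0),
      theo_mz = numeric(0), total_area = numeric(0), n_peaks = integer(0)
    )
  }
  structure(
    list(species = species, peak_map = map,
         peptide_total = spectrum$peptide_total,
         metal_total = spectrum$metal_total,
         peptide_mass = m, tol_ppm = tol_ppm),
    class = "species_assignments"
  )
}

#' @export
print.species_assignments <- function(x, ...) {
  cat(sprintf(
    "<species_assignments> %d species rows, %d/%d centroids matched\n",
    nrow(x$species), sum(x$peak_map$status == "matched"), nrow(x$peak_map)))
  invisible(x)
}

#' Quantify peptide mole fractions from assigned species
#'
#' Converts species areas into the mole fractions of peptide in the apo,
#' singly bound, and (at least) doubly bound states, assuming equal signal
#' response per species concentration. A dimer contributes two peptide
#' equivalents; nonspecific gas-phase dimers carry no silver and therefore
#' feed the apo pool. Species with `n_ag >= 2` are pooled into `f2` for the
#' two-site fit.
#'
#' @param assignments A [assign_species()] result.
#' @param response_factors Optional named numeric vector of relative
#'   response factors keyed `"k<k>n<n>"` (e.g. `"k1n1"`); areas are divided
#'   by the factor before quantification. Default: all 1.
#' @return List of class `titration_quant` with `f0`, `f1`, `f2`
#'   (fractions summing to 1), `equivalents` (per Ag count), and the
#'   spectrum totals.
#' @export
quantify <- function(assignments, response_factors = NULL) {
  stopifnot(inherits(assignments, "species_assignments"))
  sp <- assignments$species
  if (nrow(sp) == 0L || sum(sp$total_area) <= 0) {
    stop("no assigned signal to quantify")
  }
  area <- sp$total_area
  if (!is.null(response_factors)) {
    key <- paste0("k", sp$oligomer_k, "n", sp$n_ag)
    rf <- response_factors[key]
    rf[is.na(rf)] <- 1
    area <- area / rf
  }
  # peptide equivalents: a k-mer ion carries k peptide units
  equiv <- area * sp$oligomer_k
  by_n <- tapply(equiv, sp$n_ag, sum)
  total <- sum(equiv)
  n_vals <- as.integer(names(by_n))
  f0 <- sum(by_n[n_vals == 0L]) / total
  f1 <- sum(by_n[n_vals == 1L]) / total
  f2 <- sum(by_n[n_vals >= 2L]) / total
  structure(
    list(
      f0 = unname(f0), f1 = unname(f1), f2 = unname(f2),
      equivalents = stats::setNames(as.numeric(by_n), names(by_n)),
      peptide_total = assignments$peptide_total,
      metal_total = assignments$metal_total
    ),
    class = "titration_quant"
  )
}

#' @export
print.titration_quant <- function(x, ...) {
  cat(sprintf(
    "<titration_quant> f0 %.3f, f1 %.3f, f2 %.3f (Ag+ %.4g / peptide %.4g uM)\n",
    x$f0, x$f1, x$f2, x$metal_total, x$peptide_total))
  invisible(x)
}

#' Fit stepwise dissociation constants to an ESI-MS titration
#'
#' Least-squares fit of the sequential two-site model to observed mole
#' fractions across titration points: minimizes the sum over points of
#' `(f0 - f0_model)^2 + (f1 - f1_model)^2 + (f2 - f2_model)^2`, where the
#' model fractions come from [solve_species()] at each point's totals. The
#' search is over `log(kd1), log(kd2)` from the fixed documented starting
#' point (1 uM, 10 uM), so results are deterministic.
#'
#' When the peptide concentration far exceeds `kd1`, the data constrain
#' `kd1` only weakly (the first site is saturated at every measurable
#' point); the fit then reports `kd1_identifiable = FALSE` and `kd1_hat`
#' should be read as an upper bound.
#'
#' @param quants List of [quantify()] results (>= 3 points, at least one
#'   with metal present).
#' @param init A [binding_model()] giving the starting point; default
#'   `binding_model(1, 10)`.
#' @return List of class `fit_result`: `kd1_hat`, `kd2_hat` (uM), `sse`,
#'   `converged`, `kd1_identifiable`.
#' @export
fit_kds <- function(quants, init = binding_model(1, 10)) {
  stopifnot(is.list(quants), length(quants) >= 3L,
            inherits(init, "binding_model"))
  for (q in quants) stopifnot(inherits(q, "titration_quant"))
  mt <- vapply(quants, function(q) q$metal_total, numeric(1))
  if (!any(mt > 0)) stop("need at least one titration point with Ag+ added")
  obs <- t(vapply(quants, function(q) c(q$f0, q$f1, q$f2), numeric(3)))
  totals <- t(vapply(quants, function(q) c(q$peptide_total, q$metal_total),
                     numeric(2)))
  objective <- function(logk) {
    model <- binding_model(exp(logk[1]), exp(logk[2]))
    sse <- 0
    for (i in seq_len(nrow(obs))) {
      s <- solve_species(model, totals[i, 1], totals[i, 2])
      fm <- c(s$p_free, s$pag, s$pag2) / totals[i, 1]
      sse <- sse + sum((obs[i, ] - fm)^2)
    }
    sse
  }
  fit <- stats::optim(log(c(init$kd1, init$kd2)), objective,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  # one deterministic restart from the first solution tightens convergence
  fit2 <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  if (fit2$value <= fit$value) fit <- fit2
  kd1_hat <- exp(fit$par[1])
  kd2_hat <- exp(fit$par[2])
  # identifiability probe: doubling kd1 must move the objective measurably
  sens <- objective(c(log(2 * kd1_hat), log(kd2_hat))) - fit$value
  structure(
    list(
      kd1_hat = kd1_hat, kd2_hat = kd2_hat, sse = fit$value,
      converged = fit$convergence == 0,
      kd1_identifiable = sens > 1e-8
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> KD1 = %.4g uM%s, KD2 = %.4g uM (SSE %.3e, %s)\n",
    x$kd1_hat, if (x$kd1_identifiable) "" else " (upper bound)",
    x$kd2_hat, x$sse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
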