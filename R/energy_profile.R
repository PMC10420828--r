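# Assembly of reaction energy profiles from per-stationary-point
# component records, relaxed-scan maxima, and Eyring transition-state
# theory rate/barrier interconversion.

# pinned physical constants (kcal, mol, K, s); versioned so outputs
# can record exactly which set produced them
MECHPROF_CONSTANTS <- list(
  id = "pinned-v1",
  R_kcal = 1.987204e-3,        # gas constant, kcal mol^-1 K^-1
  kB_over_h = 2.083661e10      # Boltzmann/Planck ratio, s^-1 K^-1
)

#' Physical constants used by the Eyring conversions
#' @return named list with `id`, `R_kcal` (kcal/mol/K) and
#'   `kB_over_h` (1/s/K).
#' @export
mechprof_constants <- function() MECHPROF_CONSTANTS

solv_column <- function(epsilon) {
  if (!epsilon %in% c(4, 80)) stop("epsilon must be 4 or 80")
  paste0("E_solv_eps", epsilon)
}

#' Composite energy of one stationary point
#'
#' The composite (final) energy of a state, relative to the initial
#' state, is the sum of the large-basis relative electronic energy,
#' the solvation-energy difference at the chosen dielectric, and the
#' relative zero-point energy:
#' `E = dE_LB + dE_solv(eps) + dZPE` (kcal/mol).
#'
#' @param components named list or one-row data.frame with `E_LB`,
#'   `E_solv_eps4` and/or `E_solv_eps80`, and `ZPE`, all already
#'   relative to the initial state.
#' @param epsilon dielectric constant, 4 or 80 (default 4).
#' @return kcal/mol.
#' @export
composite_energy <- function(components, epsilon = 4) {
  need <- c("E_LB", solv_column(epsilon), "ZPE")
  for (cn in need) {
    v <- components[[cn]]
    if (is.null(v) || is.na(v))
      stop("missing required component: ", cn)
  }
  components[["E_LB"]] + components[[solv_column(epsilon)]] + components[["ZPE"]]
}

# pull one model's states out of an energy_record_table and
# relativize absolute-mode columns against the initial state
relative_components <- function(table, model_id, epsilon) {
  rows <- table[table$model_id == model_id, , drop = FALSE]
  if (!nrow(rows)) stop("no records for model '", model_id, "'")
  missing_states <- setdiff(STATE_LABELS, rows$state)
  if (length(missing_states))
    stop("model '", model_id, "' is missing state(s): ",
         paste(missing_states, collapse = ", "))
  modes <- attr(table, "modes")
  cols <- intersect(ENERGY_COLUMNS, names(rows))
  ini <- rows[rows$state == "initial", , drop = FALSE]
  out <- rows[match(STATE_LABELS, rows$state), c("model_id", "state", cols)]
  for (cn in cols)
    if (modes[[cn]] == "absolute") out[[cn]] <- out[[cn]] - ini[[cn]]
  rownames(out) <- NULL
  out
}

#' Assemble a reaction energy profile
#'
#' Builds the initial/TS/final composite-energy profile of one model
#' at the chosen dielectric; absolute-mode solvation columns are
#' relativized against the same model's initial state.  The barrier
#' is `E(TS) - E(initial)` and the reaction energy
#' `E(final) - E(initial)`; the reaction is labelled exoenergetic when
#' the reaction energy is negative.
#'
#' @param table [energy_record_table()] holding `initial`, `TS` and
#'   `final` rows for `model_id`.
#' @param model_id model identifier.
#' @param epsilon dielectric constant, 4 or 80 (default 4; the
#'   headline low-dielectric protein-interior choice).
#' @return object of class `reaction_profile`: list with `model_id`,
#'   `epsilon`, `energies` (named initial/TS/final, kcal/mol,
#'   initial = 0), `barrier`, `reaction_energy`, `thermicity`,
#'   `constants_id`.
#' @export
assemble_profile <- function(table, model_id, epsilon = 4) {
  rel <- relative_components(table, model_id, epsilon)
  e <- vapply(STATE_LABELS, function(s)
    composite_energy(rel[rel$state == s, , drop = FALSE], epsilon), numeric(1))
  names(e) <- STATE_LABELS
  reaction_energy <- e[["final"]] - e[["initial"]]
  structure(list(model_id = model_id, epsilon = epsilon, energies = e,
                 barrier = e[["TS"]] - e[["initial"]],
                 reaction_energy = reaction_energy,
                 thermicity = if (reaction_energy < 0) "exoenergetic"
                 else if (reaction_energy > 0) "endoenergetic" else "neutral",
                 constants_id = MECHPROF_CONSTANTS$id),
            class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("reaction_profile %s (eps = %g):\n", x$model_id, x$epsilon))
  cat(sprintf("  %-8s %6.1f kcal/mol\n", names(x$energies), x$energies), sep = "")
  cat(sprintf("  barrier %.1f kcal/mol, reaction energy %.1f kcal/mol (%s)\n",
              x$barrier, x$reaction_energy, x$thermicity))
  invisible(x)
}

#' Plot a reaction energy profile
#'
#' Step-style initial/TS/final profile in the manner of standard
#' cluster-approach mechanism figures.
#'
#' @param x `reaction_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reaction_profile <- function(x, ...) {
  e <- x$energies
  xs <- c(1, 2, 3)
  graphics::plot(xs, e, type = "n", xaxt = "n", xlab = "reaction coordinate",
                 ylab = "relative energy (kcal/mol)",
                 main = sprintf("%s (eps = %g)", x$model_id, x$epsilon), ...)
  graphics::segments(xs - 0.25, e, xs + 0.25, e, lwd = 3)
  graphics::segments(xs[-3] + 0.25, e[-3], xs[-1] - 0.25, e[-1], lty = 2)
  graphics::axis(1, at = xs, labels = names(e))
  graphics::text(xs, e, sprintf("%.1f", e), pos = 3)
  invisible(x)
}

#' Serialize a reaction profile to JSON
#' @param profile `reaction_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Maximum of a relaxed potential-energy scan
#'
#' Returns the scan point of maximal relative energy; ties are broken
#' toward the smaller constrained distance.
#'
#' @param points data.frame with columns `distance` (Angstrom) and
#'   `energy` (kcal/mol relative to the reactant).
#' @return list with `distance` and `energy` of the maximum.
#' @export
scan_maximum <- function(points) {
  if (!nrow(points)) stop("empty scan")
  if (any(points$distance <= 0)) stop("scan distances must be positive")
  best <- which(points$energy == max(points$energy))
  if (length(best) > 1L) best <- best[which.min(points$distance[best])]
  list(distance = points$distance[best], energy = points$energy[best])
}

#' Eyring conversions between rate constant and free-energy barrier
#'
#' Transition-state theory with transmission coefficient 1:
#' `k = (kB*T/h) * exp(-dG/(R*T))`, so
#' `dG = R*T*ln(kB*T/(h*k))`.  Constants are pinned
#' ([mechprof_constants()]); temperature defaults to 303 K, the
#' enzyme's activity temperature.
#'
#' @param rate first-order rate constant in 1/s.
#' @param temperature absolute temperature in K.
#' @return free-energy barrier in kcal/mol.
#' @export
eyring_barrier_from_rate <- function(rate, temperature = 303) {
  if (any(rate <= 0)) stop("rate must be positive")
  if (any(temperature <= 0)) stop("temperature must be positive")
  with(MECHPROF_CONSTANTS,
       R_kcal * temperature * log(kB_over_h * temperature / rate))
}

#' @rdname eyring_barrier_from_rate
#' @param barrier free-energy barrier in kcal/mol.
#' @return rate constant in 1/s.
#' @export
eyring_rate_from_barrier <- function(barrier, temperature = 303) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  with(MECHPROF_CONSTANTS,
       kB_over_h * temperature * exp(-barrier / (R_kcal * temperature)))
}

#' Solvation-energy trend across the reaction
#'
#' Orders a model's states by decreasing absolute solvation energy at
#' the chosen dielectric.  Requires absolute-mode solvation values
#' (a relative-mode table cannot give magnitudes).
#'
#' @inheritParams assemble_profile
#' @return list with `states` (labels in decreasing |E_solv| order)
#'   and `tied` (TRUE when any two magnitudes are equal; ordering is
#'   then the stable initial/TS/final input order).
#' @export
solvation_trend <- function(table, model_id, epsilon = 4) {
  cn <- solv_column(epsilon)
  modes <- attr(table, "modes")
  if (is.null(modes[[cn]]) || modes[[cn]] != "absolute")
    stop("solvation trend needs absolute-mode ", cn, " values")
  rows <- table[table$model_id == model_id, , drop = FALSE]
  rows <- rows[match(STATE_LABELS, rows$state), , drop = FALSE]
  if (anyNA(rows$state)) stop("model '", model_id, "' lacks a full profile")
  mag <- abs(rows[[cn]])
  ord <- order(-mag)   # stable: ties keep input (initial, TS, final) order
  list(states = rows$state[ord], tied = anyDuplicated(mag) > 0)
}
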