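#' Specification of a multi-experiment growth-rate table
#'
#' Describes the statistical structure the hierarchical growth-rate model
#' assumes: fixed cell-type and plate-type effects on the specific growth
#' rate, a random experiment-date effect shared by all wells of one
#' experiment, and plate-type-specific residual noise.
#'
#' @param cell_levels,plate_levels character vectors of factor levels; the
#'   first level of each is the reference (zero offset convention is not
#'   required -- effects are given per level).
#' @param mu baseline growth rate per hour (grand mean for the first cell
#'   and plate level when their effects are zero).
#' @param cell_effects,plate_effects named numeric vectors of per-level
#'   mean growth-rate offsets (per hour); every level must have an entry.
#' @param exp_sd SD of the random experiment-date effect (per hour, >= 0).
#' @param residual_sd_by_plate named numeric vector, per-plate-type
#'   residual SD (>= 0); every plate level must have an entry.
#' @param n_experiments number of experiment dates (each contributes one
#'   plate of every type).
#' @param n_replicates wells per (experiment, cell, plate) combination.
#' @param seed integer RNG seed.
#' @return an object of class `"effects_table_spec"`.
#' @export
effects_table_spec <- function(cell_levels = c("HCT116", "HT29"),
                               plate_levels = c("plastic", "softwell_0.2kPa",
                                                "softwell_2kPa"),
                               mu = 0.030,
                               cell_effects = c(HCT116 = 0, HT29 = -0.005),
                               plate_effects = c(plastic = 0,
                                                 softwell_0.2kPa = -0.010,
                                                 softwell_2kPa = -0.004),
                               exp_sd = 0.003,
                               residual_sd_by_plate = c(plastic = 0.002,
                                                        softwell_0.2kPa = 0.004,
                                                        softwell_2kPa = 0.004),
                               n_experiments = 6L, n_replicates = 4L,
                               seed = 1L) {
  stopifnot(is.character(cell_levels), is.character(plate_levels),
            length(cell_levels) >= 1L, length(plate_levels) >= 1L,
            is.numeric(mu), exp_sd >= 0,
            n_experiments >= 1L, n_replicates >= 1L)
  miss <- setdiff(cell_levels, names(cell_effects))
  if (length(miss)) stop("cell_effects missing level(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(plate_levels, names(plate_effects))
  if (length(miss)) stop("plate_effects missing level(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(plate_levels, names(residual_sd_by_plate))
  if (length(miss)) stop("residual_sd_by_plate missing level(s): ", paste(miss, collapse = ", "))
  if (any(residual_sd_by_plate < 0)) stop("residual SDs must be >= 0")
  structure(list(cell_levels = cell_levels, plate_levels = plate_levels,
                 mu = mu, cell_effects = cell_effects,
                 plate_effects = plate_effects, exp_sd = exp_sd,
                 residual_sd_by_plate = residual_sd_by_plate,
                 n_experiments = as.integer(n_experiments),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "effects_table_spec")
}

#' Generate a synthetic multi-experiment growth-rate table
#'
#' Draws growth rates `y = mu + cell effect + plate effect + u_exp + eps`
#' with `u_exp ~ N(0, exp_sd^2)` shared within an experiment date and
#' `eps ~ N(0, residual_sd_by_plate^2)` per well, for every combination of
#' experiment, cell level, plate level and replicate.  Ground-truth
#' effects (including the realized experiment effects) are attached so
#' recovery can be tested.
#'
#' @param spec an [effects_table_spec()] object.
#' @return a data.frame of class `"experiment_table"` with columns
#'   `experiment`, `cell`, `plate`, `replicate`, `rate`, and attribute
#'   `truth` (list: `mu`, `cell_effects`, `plate_effects`, `u_exp`,
#'   `exp_sd`, `residual_sd_by_plate`).
#' @export
gen_effects_table <- function(spec) {
  stopifnot(inherits(spec, "effects_table_spec"))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      plate = spec$plate_levels,
                      cell = spec$cell_levels,
                      experiment = paste0("exp", seq_len(spec$n_experiments)),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("experiment", "cell", "plate", "replicate")]
  out <- with_substream(spec$seed, "effects_table", {
    u <- rnorm(spec$n_experiments, 0, spec$exp_sd)
    names(u) <- paste0("exp", seq_len(spec$n_experiments))
    res_sd <- spec$residual_sd_by_plate[grid$plate]
    y <- spec$mu + spec$cell_effects[grid$cell] +
      spec$plate_effects[grid$plate] + u[grid$experiment] +
      rnorm(nrow(grid), 0, res_sd)
    list(y = unname(y), u = u)
  })
  grid$rate <- out$y
  structure(grid, class = c("experiment_table", "data.frame"),
            truth = list(mu = spec$mu, cell_effects = spec$cell_effects,
                         plate_effects = spec$plate_effects, u_exp = out$u,
                         exp_sd = spec$exp_sd,
                         residual_sd_by_plate = spec$residual_sd_by_plate))
}

#' Generate a synthetic per-experiment IC50 table
#'
#' Draws replicate IC50s for one cell line across oxygen conditions with
#' a planted fold change: log IC50 in condition `o2` equals
#' `log(base_ic50) + log(fold[o2])` plus Gaussian replicate noise on the
#' log scale (i.e. lognormal IC50s).  Used to test whether
#' [fit_ic50_difference_model()] recovers a known hypoxia effect.
#'
#' @param base_ic50 IC50 (uM) at the reference (normoxia) condition.
#' @param fold named numeric vector of true fold changes for the
#'   non-reference oxygen levels.
#' @param n_per_group replicate experiments per condition.
#' @param sdlog SD of replicate noise on the log-IC50 scale.
#' @param cell cell-line label.
#' @param reference label of the normoxia condition.
#' @param seed integer RNG seed.
#' @return data.frame with columns `ic50`, `cell`, `o2`, `experiment`,
#'   and attribute `truth`.
#' @export
gen_ic50_table <- function(base_ic50 = 0.6, fold = c("1%" = 1, "0.1%" = 1.7),
                           n_per_group = 6L, sdlog = 0.25, cell = "HCT116",
                           reference = "21%", seed = 1L) {
  stopifnot(base_ic50 > 0, all(fold > 0), n_per_group >= 2L, sdlog >= 0)
  o2 <- rep(c(reference, names(fold)), each = n_per_group)
  mu <- log(base_ic50) + log(c(setNames(1, reference), fold))[o2]
  ic50 <- with_substream(seed, "ic50_table",
                         exp(mu + rnorm(length(mu), 0, sdlog)))
  structure(data.frame(ic50 = unname(ic50), cell = cell, o2 = o2,
                       experiment = paste0("exp", seq_along(o2)),
                       stringsAsFactors = FALSE),
            truth = list(base_ic50 = base_ic50, fold = fold, sdlog = sdlog))
}
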