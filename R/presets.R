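## Named presets reproducing the published hyperparameter tables: "dw"
## (2D double well), "gmm" (Gaussian mixture, 4- or 20-dimensional) and
## "ala" (molecular-scale settings; the corresponding potential is external
## and not shipped).

#' List or fetch training presets
#'
#' Each preset bundles the architecture (flow layers, conditioner size,
#' spline knots and interval), the optimizer settings and the tempering
#' schedule used for the corresponding benchmark system.
#'
#' @param name preset name (`"dw"`, `"gmm"`, `"ala"`); `NULL` lists all.
#' @param dim_x,dim_z optional dimension overrides (gmm/ala).
#' @return a list with components `model` (arguments for [cg_model()]),
#'   `schedule` (a `tempering_schedule`), `config` (a `train_config`), or a
#'   data frame of all presets when `name` is `NULL`.
#' @export
preset <- function(name = NULL, dim_x = NULL, dim_z = NULL) {
  tab <- list(
    dw = list(
      model = list(dim_x = 2L, dim_z = 1L, block_size = 1L, n_layers = 6L,
                   n_knots = 8L, interval = 5, flow_width = 32L,
                   flow_depth = 2L, cond_width = 32L, cond_depth = 2L),
      schedule = tempering_schedule(beta0 = 0.01, beta_target = 1,
                                    dkl_max = 0.1, dbeta_max = 0.05),
      config = train_config(n_samples = 500L, L = 100L, L_initial = 4900L,
                            lr = 1e-3)),
    gmm = list(
      model = list(dim_x = 4L, dim_z = 2L, block_size = 1L, n_layers = 8L,
                   n_knots = 8L, interval = 4, flow_width = 40L,
                   flow_depth = 2L, cond_width = 40L, cond_depth = 2L),
      schedule = tempering_schedule(beta0 = 0.001, beta_target = 1,
                                    dkl_max = 0.1, dbeta_max = 0.02),
      config = train_config(n_samples = 10000L, L = 1000L,
                            L_initial = 19000L, lr = 1e-3)),
    ala = list(
      model = list(dim_x = 24L, dim_z = 15L, block_size = 3L, n_layers = 8L,
                   n_knots = 8L, interval = 4, flow_width = 64L,
                   flow_depth = 4L, cond_width = 90L, cond_depth = 8L),
      schedule = tempering_schedule(beta0 = 1e-4, beta_target = 1,
                                    dkl_max = 0.1, dbeta_max = 0.005),
      config = train_config(n_samples = 10000L, L = 1000L,
                            L_initial = 15000L, lr = 5e-4, skip_clip = TRUE))
  )
  if (is.null(name)) {
    return(data.frame(
      preset = names(tab),
      dim_x = vapply(tab, function(p) p$model$dim_x, 1L),
      dim_z = vapply(tab, function(p) p$model$dim_z, 1L),
      flow_layers = vapply(tab, function(p) p$model$n_layers, 1L),
      knots = vapply(tab, function(p) p$model$n_knots, 1L),
      interval = vapply(tab, function(p) p$model$interval, 1),
      N = vapply(tab, function(p) p$config$n_samples, 1L),
      L = vapply(tab, function(p) p$config$L, 1L),
      L_initial = vapply(tab, function(p) p$config$L_initial, 1L),
      lr = vapply(tab, function(p) p$config$lr, 1),
      beta0 = vapply(tab, function(p) p$schedule$beta0, 1),
      dbeta_max = vapply(tab, function(p) p$schedule$dbeta_max, 1),
      dkl_max = vapply(tab, function(p) p$schedule$dkl_max, 1)
    ))
  }
  if (!name %in% names(tab)) stop("unknown preset: ", name)
  p <- tab[[name]]
  if (!is.null(dim_x)) p$model$dim_x <- as.integer(dim_x)
  if (!is.null(dim_z)) p$model$dim_z <- as.integer(dim_z)
  p
}
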