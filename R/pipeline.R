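# End-to-end pipeline: simulated screen -> masks -> features -> training ->
# distances -> 4PL dose-response.

#' Profile one well: stack to aggregated feature row
#'
#' Runs [segment_well()] and [extract_organoid_features()] /
#' [aggregate_well()] on a single stack.
#'
#' @param stack An `image_stack`.
#' @param layout_row One-row layout data.frame for the well.
#' @param ... Passed to [segment_well()].
#' @return One-row profile data.frame.
#' @export
profile_well <- function(stack, layout_row, ...) {
  masks <- segment_well(stack, ...)
  rec <- extract_organoid_features(masks,
                                   pixel_size = stack$acquisition$pixel_size,
                                   well_id = stack$well_id)
  suppressWarnings(aggregate_well(rec, layout_row))
}

#' Simulate a screen and compute per-well profiles (streaming)
#'
#' Generates each well's stack with [generate_well_stack()], profiles it
#' immediately and discards the pixels, keeping memory flat even for full
#' plates.
#'
#' @inheritParams generate_screen
#' @param verbose Print progress every 25 wells.
#' @param ... Passed to [segment_well()].
#' @return A list with `profiles` (data.frame, one row per well including
#'   layout metadata and `theta`), `truth` and `layout`.
#' @export
screen_profiles <- function(design, compounds,
                            base_pheno = phenotype_params(),
                            acq = acquisition_params(), seed = 1,
                            verbose = FALSE, ...) {
  if (inherits(compounds, "compound_model")) compounds <- list(compounds)
  layout <- screen_layout(design, compounds)
  layout$theta <- 0
  cmp_by_name <- stats::setNames(compounds,
                                 vapply(compounds, `[[`, "", "name"))
  trt <- layout$role == "treated"
  layout$theta[trt] <- mapply(function(cn, d)
    hill_phenotype(d, cmp_by_name[[cn]]),
    layout$compound[trt], layout$dose_nM[trt])
  layout$seed <- well_seed(seed, seq_len(nrow(layout)))

  profs <- vector("list", nrow(layout))
  truths <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ph <- base_pheno
    ph$theta <- layout$theta[i]
    res <- generate_well_stack(ph, acq, layout$seed[i],
                               well_id = layout$well[i])
    truths[[i]] <- res$truth
    profs[[i]] <- profile_well(res$stack, layout[i, ], ...)
    if (verbose && i %% 25 == 0)
      message("profiled ", i, "/", nrow(layout), " wells")
  }
  profiles <- do.call(rbind, profs)
  profiles$replicate <- layout$replicate
  profiles$theta <- layout$theta
  list(profiles = profiles, truth = do.call(rbind, truths), layout = layout)
}

#' Analyse a profiled screen: train, score and fit
#'
#' Trains the discriminating feature space between the vehicle controls and
#' the high-dose wells ([train_feature_space()]), scores every well
#' ([score_well()]), and fits each compound's 4PL dose-response on the
#' per-well distances ([fit_4pl()]), using the scored control wells' SD for
#' the dynamic-range no-fit rule.
#'
#' With the default `train_scope = "line"` one feature space is trained per
#' plate (organoid line) against the pooled top-dose wells of all screened
#' compounds — the larger training set makes selection markedly more stable
#' than per-compound training, which is still available as
#' `train_scope = "compound"`.
#'
#' @param profiles Profile data.frame covering one or more compounds plus
#'   controls.
#' @param control_label Control condition label (default `"DMSO"`).
#' @param k Number of selected features (default 10).
#' @param strategy Feature-selection strategy, see [train_feature_space()].
#' @param train_scope `"line"` (one selection for the whole plate, default)
#'   or `"compound"` (one selection per compound).
#' @return A list with `fits` (named list of `fit_result` per compound),
#'   `table` (data.frame `compound, ec50_nM, hill, bottom, top, r_squared,
#'   status`), `distances` (well-level distances) and `selections` (named
#'   list of `feature_selection`).
#' @export
analyze_screen <- function(profiles, control_label = "DMSO", k = 10,
                           strategy = "best_separating",
                           train_scope = c("line", "compound")) {
  train_scope <- match.arg(train_scope)
  is_ctrl <- profiles$compound == control_label | profiles$role == "control"
  compounds <- setdiff(unique(profiles$compound[!is_ctrl]), control_label)
  fits <- list(); sels <- list(); dists <- list()
  if (train_scope == "line") {
    sel_all <- train_feature_space(profiles, control_label = control_label,
                                   k = k, strategy = strategy)
    sc_all <- score_plate(profiles, sel_all)
  }
  for (cmp in compounds) {
    if (train_scope == "compound") {
      sub <- profiles[is_ctrl | profiles$compound == cmp, , drop = FALSE]
      sel <- train_feature_space(sub, control_label = control_label, k = k,
                                 strategy = strategy)
      sc <- score_plate(sub, sel)
    } else {
      sel <- sel_all
      sc <- sc_all
    }
    ctl_d <- sc$distances$distance[sc$distances$compound == control_label]
    trt <- sc$distances[sc$distances$compound == cmp, , drop = FALSE]
    fit <- fit_4pl(trt$dose_nM, trt$distance,
                   control_sd = if (length(ctl_d) > 1) stats::sd(ctl_d)
                   else NULL,
                   bottom_min = 0)
    fits[[cmp]] <- fit
    sels[[cmp]] <- sel
    dists[[cmp]] <- sc$distances
  }
  table <- do.call(rbind, lapply(compounds, function(cmp) {
    f <- fits[[cmp]]
    data.frame(compound = cmp,
               ec50_nM = if (f$status == "fit") f$ec50 else NA_real_,
               hill = f$hill, bottom = f$bottom, top = f$top,
               r_squared = f$r_squared, status = f$status)
  }))
  list(fits = fits, table = table,
       distances = unique(do.call(rbind, dists)), selections = sels)
}

#' Simulate and analyse a full screen in one call
#'
#' Convenience wrapper chaining [screen_profiles()] and [analyze_screen()].
#'
#' @inheritParams screen_profiles
#' @inheritParams analyze_screen
#' @param ... Passed to [segment_well()].
#' @return The [analyze_screen()] result, plus `profiles` and `truth`.
#' @export
run_screen <- function(design, compounds, base_pheno = phenotype_params(),
                       acq = acquisition_params(), seed = 1,
                       control_label = "DMSO", k = 10,
                       strategy = "best_separating", verbose = FALSE, ...) {
  sp <- screen_profiles(design, compounds, base_pheno, acq, seed,
                        verbose = verbose, ...)
  out <- analyze_screen(sp$profiles, control_label = control_label, k = k,
                        strategy = strategy)
  out$profiles <- sp$profiles
  out$truth <- sp$truth
  out
}
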