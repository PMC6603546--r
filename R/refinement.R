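#' Energy-minimization configuration
#'
#' @param lambda1 weight of the data-fidelity term `E1` (default 0.2).
#' @param lambda2 weight of the bone-length-constraint term `E2`
#'   (default 8.25). Both defaults come from a grid search reported for
#'   this refinement scheme.
#' @param sigma width (in frames) of the Gaussian mapping the
#'   consecutive-inadequacy score to the prediction weight (default 3).
#' @param max_iter quasi-Newton iteration cap per frame (default 500).
#' @param reltol relative convergence tolerance passed to the optimizer.
#' @param eps guard length (meters) below which a candidate bone is treated
#'   as degenerate when forming gradients.
#' @param swap_uw swap the roles of the observation and prediction weights
#'   in `E1`. The default weighting anchors a joint to its prediction when
#'   its score is 0 and to its observation when the score is large; set
#'   `TRUE` to invert that. Escape hatch only — not used by the shipped
#'   defaults or the acceptance checks.
#' @return a list of class `energy_config`.
#' @export
energy_config <- function(lambda1 = 0.2, lambda2 = 8.25, sigma = 3,
                          max_iter = 500L, reltol = 1e-10, eps = 1e-9,
                          swap_uw = FALSE) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, sigma > 0, max_iter >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma = sigma,
                 max_iter = as.integer(max_iter), reltol = reltol,
                 eps = eps, swap_uw = isTRUE(swap_uw)),
            class = "energy_config")
}

#' Prediction/observation weights from the inadequacy score
#'
#' `u = exp(-k^2 / (2 sigma^2))`, `w = 1 - u`; `u` weights the prediction
#' anchor and `w` the observation anchor in `E1`, and they sum to 1 exactly.
#'
#' @param k non-negative inadequacy score(s).
#' @param sigma Gaussian width in frames (default 3).
#' @return list with numeric vectors `u` and `w`.
#' @examples
#' joint_weights(0)  # u = 1, w = 0
#' joint_weights(3)  # u = exp(-1/2)
#' @export
joint_weights <- function(k, sigma = 3) {
  stopifnot(all(k >= 0), sigma > 0)
  u <- exp(-k^2 / (2 * sigma^2))
  list(u = u, w = 1 - u)
}

#' Refinement energy of a candidate pose
#'
#' `E = lambda1 * E1 + lambda2 * E2` where
#' `E1 = sum_i (w_i ||v_i - vhat_i||^2 + u_i ||p_i - vhat_i||^2)` anchors
#' each candidate joint to its observation and its prediction, and
#' `E2 = sum_bones (l(vhat) - l_ref)^2` penalizes deviations of candidate
#' bone lengths from the class reference lengths (symmetry enters through
#' the shared class references). Joints without a prediction (`NA` rows in
#' `predicted`) contribute only their observation term.
#'
#' @param vhat candidate positions, `n_joints x 3`.
#' @param observed observed positions, `n_joints x 3`.
#' @param predicted combined predictions, `n_joints x 3` with `NA` rows
#'   allowed, or `NULL`.
#' @param u,w per-joint weights (see [joint_weights()]).
#' @param refs a complete `bone_reference_table`.
#' @param dialect a `skeleton_dialect`.
#' @param config an [energy_config()].
#' @return named numeric vector `c(E, E1, E2)`.
#' @export
pose_energy <- function(vhat, observed, predicted, u, w, refs, dialect,
                        config = energy_config()) {
  l_ref <- ref_by_bone(refs, dialect)
  terms <- .energy_terms(vhat, observed, predicted, u, w, l_ref,
                         dialect$edge_idx, config)
  c(E = config$lambda1 * terms$E1 + config$lambda2 * terms$E2,
    E1 = terms$E1, E2 = terms$E2)
}

.energy_terms <- function(vhat, observed, predicted, u, w, l_ref, edge_idx,
                          config) {
  if (config$swap_uw) { tmp <- u; u <- w; w <- tmp }
  E1 <- sum(w * rowSums((observed - vhat)^2))
  if (!is.null(predicted)) {
    has_p <- is.finite(predicted[, 1L])
    if (any(has_p))
      E1 <- E1 + sum(u[has_p] *
                     rowSums((predicted[has_p, , drop = FALSE] -
                              vhat[has_p, , drop = FALSE])^2))
  }
  d <- vhat[edge_idx[, 2L], , drop = FALSE] -
       vhat[edge_idx[, 1L], , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  E2 <- sum((l - l_ref)^2)
  list(E1 = E1, E2 = E2, l = l, d = d)
}

.energy_gradient <- function(vhat, observed, predicted, u, w, l_ref,
                             edge_idx, config) {
  if (config$swap_uw) { tmp <- u; u <- w; w <- tmp }
  g <- 2 * config$lambda1 * w * (vhat - observed)
  if (!is.null(predicted)) {
    has_p <- is.finite(predicted[, 1L])
    if (any(has_p))
      g[has_p, ] <- g[has_p, ] +
        2 * config$lambda1 * u[has_p] *
        (vhat[has_p, , drop = FALSE] - predicted[has_p, , drop = FALSE])
  }
  d <- vhat[edge_idx[, 2L], , drop = FALSE] -
       vhat[edge_idx[, 1L], , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  coef <- 2 * config$lambda2 * (l - l_ref) / pmax(l, config$eps)
  for (k in seq_len(nrow(edge_idx))) {
    gk <- coef[k] * d[k, ]
    g[edge_idx[k, 2L], ] <- g[edge_idx[k, 2L], ] + gk
    g[edge_idx[k, 1L], ] <- g[edge_idx[k, 1L], ] - gk
  }
  g
}

#' Refine a single frame by constrained energy minimization
#'
#' Minimizes [pose_energy()] over all joint coordinates with a quasi-Newton
#' (BFGS) solver using the analytic gradient. The optimization starts from
#' the observation for reliable joints and from the combined prediction for
#' unreliable ones. If the solver fails, the initialization is returned and
#' flagged; the energy of the returned pose never exceeds the energy of the
#' initialization.
#'
#' @param pose a `frame_pose` (the raw observation).
#' @param trust per-joint trust data frame with columns `reliable`,
#'   `k_score` and prediction columns `pred_x`, `pred_y`, `pred_z`
#'   (`NA` when no prediction exists), as produced inside
#'   [refine_sequence()]; pass `NULL` to treat every joint as reliable with
#'   score 0 and no prediction.
#' @param refs a complete `bone_reference_table`.
#' @param config an [energy_config()].
#' @return list of class `refined_frame`: `pos` (refined `n_joints x 3`),
#'   `energy_initial`, `energy_final`, `E1`, `E2`, per-joint `u` and `w`,
#'   and `convergence` (0 = converged, as in [stats::optim()]; -1 = solver
#'   error, initialization returned).
#' @export
refine_frame <- function(pose, trust = NULL, refs, config = energy_config()) {
  d <- pose$dialect
  nj <- d$n_joints
  if (is.null(trust))
    trust <- data.frame(reliable = rep(TRUE, nj), k_score = 0L,
                        pred_x = NA_real_, pred_y = NA_real_,
                        pred_z = NA_real_)
  predicted <- as.matrix(trust[, c("pred_x", "pred_y", "pred_z")])
  dimnames(predicted) <- NULL
  has_p <- is.finite(predicted[, 1L])
  jw <- joint_weights(trust$k_score, config$sigma)
  u <- jw$u; w <- jw$w
  u[!has_p] <- 0; w[!has_p] <- 1   # no prediction: observation anchor only

  init <- pose$pos
  dimnames(init) <- NULL
  repl <- !trust$reliable & has_p
  init[repl, ] <- predicted[repl, ]

  l_ref <- ref_by_bone(refs, d)
  edge_idx <- d$edge_idx
  obs <- pose$pos
  dimnames(obs) <- NULL
  fn <- function(par) {
    v <- matrix(par, nj, 3L)
    terms <- .energy_terms(v, obs, predicted, u, w, l_ref, edge_idx, config)
    config$lambda1 * terms$E1 + config$lambda2 * terms$E2
  }
  gr <- function(par) {
    v <- matrix(par, nj, 3L)
    as.vector(.energy_gradient(v, obs, predicted, u, w, l_ref, edge_idx,
                               config))
  }
  e0 <- fn(as.vector(init))
  fit <- tryCatch(
    stats::optim(as.vector(init), fn, gr, method = "BFGS",
                 control = list(maxit = config$max_iter,
                                reltol = config$reltol)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value > e0) {
    vhat <- init
    e1 <- e0
    conv <- -1L
  } else {
    vhat <- matrix(fit$par, nj, 3L)
    e1 <- fit$value
    conv <- fit$convergence
  }
  terms <- .energy_terms(vhat, obs, predicted, u, w, l_ref, edge_idx, config)
  rownames(vhat) <- d$joints
  structure(list(pos = vhat, energy_initial = e0, energy_final = e1,
                 E1 = terms$E1, E2 = terms$E2, u = u, w = w,
                 convergence = conv),
            class = "refined_frame")
}

#' Bundle of pipeline configurations
#'
#' @param init an [init_config()].
#' @param trust a [trust_config()].
#' @param energy an [energy_config()].
#' @return a list of class `refine_config`.
#' @export
refine_config <- function(init = init_config(), trust = trust_config(),
                          energy = energy_config()) {
  structure(list(init = init, trust = trust, energy = energy),
            class = "refine_config")
}

#' Refine a whole skeleton sequence
#'
#' Runs the full pipeline: (1) reference bone lengths are estimated from the
#' initialization window; (2) each frame is assessed for trust; (3) joint
#' positions are predicted by the combined forward/backward scheme — the
#' forward side extrapolates the already-refined past, the backward side the
#' raw future, which is why refined frame `t` only exists once frame `t + 3`
#' has been ingested (a 3-frame, 0.1 s latency at 30 Hz); (4) each frame is
#' refined by [refine_frame()]. Initialization-window frames are refined
#' retrospectively with the frozen references.
#'
#' Per joint, stretches of more than 4 consecutive frames with inadequate
#' predictions are flagged `unrecovered` in the trust report rather than
#' silently interpolated.
#'
#' @param seq a `skeleton_sequence`; must be longer than
#'   `n_init_frames + 3`.
#' @param config a [refine_config()].
#' @param refs optional precomputed `bone_reference_table` (e.g., from
#'   [read_reference_table()]); estimated from the sequence when `NULL`.
#' @param batch solve all frames jointly in one optimization (offline mode;
#'   predictions for both sides then come from the raw sequence) instead of
#'   the streaming frame-by-frame solve.
#' @return list of class `refined_sequence`: `sequence` (the refined
#'   `skeleton_sequence`), `trust` (per frame and joint: reliability,
#'   reasons, `k_score`, `fb_distance`, prediction, `outlier`,
#'   `unrecovered`), `frame_log` (per frame energies and convergence),
#'   `refs`, and `config`.
#' @export
refine_sequence <- function(seq, config = refine_config(), refs = NULL,
                            batch = FALSE) {
  d <- seq$dialect
  nf <- n_frames(seq)
  nj <- d$n_joints
  min_len <- config$init$n_init_frames + 4L
  if (nf < min_len)
    stop("sequence too short: need at least n_init_frames + 4 = ", min_len,
         " frames, got ", nf)
  dt <- sequence_dt(seq)
  if (is.null(refs))
    refs <- reference_lengths(seq, config$init)
  if (batch)
    return(.refine_batch(seq, config, refs, dt))

  theta_p <- config$trust$prediction_threshold
  refined <- seq$pos
  kmat <- matrix(0L, nf, nj)
  adq <- matrix(TRUE, nf, nj)
  fbmat <- matrix(NA_real_, nf, nj)
  pred_arr <- array(NA_real_, dim = c(nf, nj, 3L))
  trust_rows <- vector("list", nf)
  frame_log <- data.frame(frame = seq_len(nf), energy_initial = NA_real_,
                          energy_final = NA_real_, E1 = NA_real_,
                          E2 = NA_real_, convergence = NA_integer_)

  for (t in seq_len(nf)) {
    fwd <- if (t >= 4L)
      3 * refined[t - 1L, , ] - 3 * refined[t - 2L, , ] + refined[t - 3L, , ]
    bwd <- if (t <= nf - 3L)
      3 * seq$pos[t + 1L, , ] - 3 * seq$pos[t + 2L, , ] + seq$pos[t + 3L, , ]
    if (!is.null(fwd) && !is.null(bwd)) {
      fb <- sqrt(rowSums((fwd - bwd)^2))
      p <- (fwd + bwd) / 2
      ad <- fb <= theta_p
      fbmat[t, ] <- fb
    } else if (!is.null(fwd) || !is.null(bwd)) {
      p <- if (is.null(fwd)) bwd else fwd
      ad <- rep(TRUE, nj)   # absence alone is never inadequate
    } else {
      p <- matrix(NA_real_, nj, 3L)
      ad <- rep(TRUE, nj)
    }
    adq[t, ] <- ad
    kprev <- if (t == 1L) integer(nj) else kmat[t - 1L, ]
    kmat[t, ] <- update_k_score(kprev, ad)
    pred_arr[t, , ] <- p

    pose <- get_frame(seq, t)
    assessed <- assess_frame(pose, refs, p, config$trust, dt)
    trust_t <- data.frame(frame = t, joint = d$joints,
                          reliable = assessed$reliable,
                          reasons = assessed$reasons,
                          k_score = kmat[t, ], fb_distance = fbmat[t, ],
                          pred_x = p[, 1L], pred_y = p[, 2L],
                          pred_z = p[, 3L], stringsAsFactors = FALSE)
    rf <- refine_frame(pose, trust_t, refs, config$energy)
    refined[t, , ] <- rf$pos
    frame_log[t, 2:6] <- list(rf$energy_initial, rf$energy_final, rf$E1,
                              rf$E2, rf$convergence)
    trust_rows[[t]] <- trust_t
  }

  trust <- do.call(rbind, trust_rows)
  trust$outlier <- as.vector(t(.outlier_matrix(kmat)))
  trust$unrecovered <- as.vector(t(.unrecovered_matrix(adq, max_run = 4L)))

  out_seq <- skeleton_sequence(seq$t, refined, seq$state, d)
  structure(list(sequence = out_seq, trust = trust, frame_log = frame_log,
                 refs = refs, config = config, dt = dt),
            class = "refined_sequence")
}

# frame x joint outlier flags: k strictly above both temporal neighbors
.outlier_matrix <- function(kmat) {
  nf <- nrow(kmat)
  out <- matrix(FALSE, nf, ncol(kmat))
  if (nf >= 3L) {
    idx <- 2:(nf - 1L)
    out[idx, ] <- kmat[idx, ] > kmat[idx - 1L, ] &
                  kmat[idx, ] > kmat[idx + 1L, ]
  }
  out
}

# frame x joint flags for inadequacy stretches longer than max_run frames
.unrecovered_matrix <- function(adq, max_run = 4L) {
  out <- matrix(FALSE, nrow(adq), ncol(adq))
  for (j in seq_len(ncol(adq))) {
    r <- rle(!adq[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > max_run)
    for (i in long) out[starts[i]:ends[i], j] <- TRUE
  }
  out
}

#' @export
print.refined_sequence <- function(x, ...) {
  cat("<refined_sequence> ", n_frames(x$sequence), " frames, dialect ",
      x$sequence$dialect$name, "\n", sep = "")
  cat("  unreliable joint-frames: ", sum(!x$trust$reliable),
      "; outliers flagged: ", sum(x$trust$outlier),
      "; unrecovered: ", sum(x$trust$unrecovered), "\n", sep = "")
  invisible(x)
}

# offline whole-sequence solve; predictions fixed from the raw sequence
.refine_batch <- function(seq, config, refs, dt) {
  d <- seq$dialect
  nf <- n_frames(seq)
  nj <- d$n_joints
  theta_p <- config$trust$prediction_threshold
  preds <- sequence_predictions(seq)
  fb <- sqrt(apply((preds$fwd - preds$bwd)^2, c(1, 2), sum))
  adq <- is.na(fb) | fb <= theta_p
  kmat <- matrix(0L, nf, nj)
  for (t in seq_len(nf)) {
    kprev <- if (t == 1L) integer(nj) else kmat[t - 1L, ]
    kmat[t, ] <- update_k_score(kprev, adq[t, ])
  }
  pred <- array(NA_real_, dim = c(nf, nj, 3L))
  both <- is.finite(preds$fwd) & is.finite(preds$bwd)
  pred[both] <- (preds$fwd[both] + preds$bwd[both]) / 2
  only_f <- is.finite(preds$fwd) & !is.finite(preds$bwd)
  pred[only_f] <- preds$fwd[only_f]
  only_b <- !is.finite(preds$fwd) & is.finite(preds$bwd)
  pred[only_b] <- preds$bwd[only_b]

  jw <- joint_weights(kmat, config$energy$sigma)
  u <- jw$u; w <- jw$w
  has_p <- is.finite(pred[, , 1L])
  u[!has_p] <- 0; w[!has_p] <- 1
  cfg <- config$energy
  l_ref <- ref_by_bone(refs, d)
  edge_idx <- d$edge_idx
  obs <- seq$pos

  fn <- function(par) {
    v <- array(par, dim = c(nf, nj, 3L))
    E1 <- sum(w * apply((obs - v)^2, c(1, 2), sum)) +
      sum((u * apply((pred - v)^2, c(1, 2), sum))[has_p])
    E2 <- 0
    for (k in seq_len(nrow(edge_idx))) {
      dd <- v[, edge_idx[k, 2L], ] - v[, edge_idx[k, 1L], ]
      l <- sqrt(rowSums(dd^2))
      E2 <- E2 + sum((l - l_ref[k])^2)
    }
    cfg$lambda1 * E1 + cfg$lambda2 * E2
  }
  gr <- function(par) {
    v <- array(par, dim = c(nf, nj, 3L))
    g <- 2 * cfg$lambda1 * array(w, dim = dim(v)) * (v - obs)
    gp <- 2 * cfg$lambda1 * array(u, dim = dim(v)) * (v - pred)
    gp[!is.finite(gp)] <- 0
    g <- g + gp
    for (k in seq_len(nrow(edge_idx))) {
      dd <- v[, edge_idx[k, 2L], ] - v[, edge_idx[k, 1L], ]
      l <- sqrt(rowSums(dd^2))
      coef <- 2 * cfg$lambda2 * (l - l_ref[k]) / pmax(l, cfg$eps)
      g[, edge_idx[k, 2L], ] <- g[, edge_idx[k, 2L], ] + coef * dd
      g[, edge_idx[k, 1L], ] <- g[, edge_idx[k, 1L], ] - coef * dd
    }
    as.vector(g)
  }
  init <- as.vector(seq$pos)
  e0 <- fn(init)
  fit <- tryCatch(
    stats::optim(init, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = cfg$max_iter)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value > e0) {
    refined <- seq$pos; e1 <- e0; conv <- -1L
  } else {
    refined <- array(fit$par, dim = c(nf, nj, 3L))
    e1 <- fit$value; conv <- fit$convergence
  }
  trust <- data.frame(
    frame = rep(seq_len(nf), each = nj),
    joint = rep(d$joints, times = nf),
    reliable = NA, reasons = "", k_score = as.vector(t(kmat)),
    fb_distance = as.vector(t(fb)),
    pred_x = as.vector(t(pred[, , 1L])),
    pred_y = as.vector(t(pred[, , 2L])),
    pred_z = as.vector(t(pred[, , 3L])),
    outlier = as.vector(t(.outlier_matrix(kmat))),
    unrecovered = as.vector(t(.unrecovered_matrix(adq, 4L))),
    stringsAsFactors = FALSE)
  out_seq <- skeleton_sequence(seq$t, refined, seq$state, d)
  structure(list(sequence = out_seq, trust = trust,
                 frame_log = data.frame(frame = NA_integer_,
                                        energy_initial = e0,
                                        energy_final = e1, E1 = NA_real_,
                                        E2 = NA_real_, convergence = conv),
                 refs = refs, config = config, dt = dt),
            class = "refined_sequence")
}

#' Pipeline latency
#'
#' The combined forward/backward prediction needs the three following
#' frames, so a refined frame lags the live stream by 3 frames.
#'
#' @param frame_rate capture rate in Hz (default 30).
#' @return latency in seconds (`3 / frame_rate`; 0.1 s at 30 Hz).
#' @export
pipeline_latency <- function(frame_rate = 30) {
  stopifnot(frame_rate > 0)
  prediction_delay_frames() / frame_rate
}

#' @rdname pipeline_latency
#' @return `prediction_delay_frames()`: the fixed 3-frame window size.
#' @export
prediction_delay_frames <- function() 3L
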