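# SEP channel pruning: dataset-level importance statistics, the geometric
# multi-loop schedule, channel selection, physical network surgery, and the
# iterative prune-retrain loop.

#' Per-loop pruning proportion of the geometric schedule
#'
#' Solving `X + (1-X)X + ... + (1-X)^(R-1) X = O` for an equal per-loop
#' proportion gives `X = 1 - (1 - O)^(1/R)`: applying `X` for `R` loops
#' removes the overall fraction `O`.
#'
#' @param O target overall pruning ratio in `[0, 1)`.
#' @param R number of prune-retrain loops (integer `>= 1`).
#' @return the per-loop proportion `X`.
#' @export
per_loop_proportion <- function(O, R) {
  if (O < 0 || O >= 1) stop("O must lie in [0, 1)")
  if (R < 1 || R %% 1 != 0) stop("R must be a positive integer")
  1 - (1 - O)^(1 / R)
}

#' Pruning schedule
#'
#' @param O target overall pruning ratio in `[0, 1)`.
#' @param R number of loops.
#' @return object of class `prune_schedule` with the derived per-loop
#'   proportion `X`.
#' @export
prune_schedule <- function(O, R = 1L) {
  structure(list(O = O, R = as.integer(R), X = per_loop_proportion(O, R)),
            class = "prune_schedule")
}

#' @export
print.prune_schedule <- function(x, ...) {
  cat(sprintf("prune schedule: O = %.3f over R = %d loop(s), X = %.4f per loop\n",
              x$O, x$R, x$X))
  invisible(x)
}

#' Accumulate dataset-level channel importance
#'
#' Runs the model in inference mode over a stream of samples and, for every
#' SEP block, averages the per-sample SE activation factors `s`:
#' `w_c = sum_j s_cj / N`.  The streaming batch-wise mean equals the mean
#' over the stacked set.
#'
#' @param model a `sep_model`.
#' @param x input tensor `(H, W, N, 3)`, a list of images, or a single
#'   image.
#' @param batch_size samples per forward pass (default 32).
#' @return named list of `channel_importance` objects (one per SEP layer):
#'   each has `layer_id`, `w` (mean activation factors) and `n_samples`.
#' @export
accumulate_importance <- function(model, x, batch_size = 32L) {
  x <- as_batch(x)
  n <- dim(x)[3]
  if (n < 1) stop("empty sample stream")
  sums <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- forward_graph(model, x[, , idx, , drop = FALSE], capture_se = TRUE)
    bs <- lapply(fw$se, colSums)
    sums <- if (is.null(sums)) bs else Map(`+`, sums, bs)
  }
  out <- lapply(names(sums), function(id)
    structure(list(layer_id = sub("\\.sep$", "", sub("^m", "", id)),
                   w = as.numeric(sums[[id]] / n), n_samples = n),
              class = "channel_importance"))
  names(out) <- vapply(out, `[[`, "", "layer_id")
  out
}

#' Select the channels to prune by proportion
#'
#' Prunes the `round(X * C)` lowest-importance channels (ascending `w`,
#' half-up rounding), always keeping at least one channel.  Ties are broken
#' by pruning the lower index first.
#'
#' @param imp a `channel_importance` (or plain numeric importance vector).
#' @param X per-loop pruning proportion in `[0, 1)`.
#' @return object of class `prune_mask`: `layer_id`, strictly increasing
#'   `kept` indices, original `C` and retained `C_p`.
#' @export
select_prune_set <- function(imp, X) {
  if (X < 0 || X >= 1) stop("X must lie in [0, 1)")
  w <- if (inherits(imp, "channel_importance")) imp$w else as.numeric(imp)
  layer <- if (inherits(imp, "channel_importance")) imp$layer_id else NA_character_
  C <- length(w)
  n_prune <- min(C - 1L, round_half_up(X * C))
  ord <- order(w, seq_along(w))         # ascending; ties -> lower index first
  pruned <- if (n_prune > 0) ord[seq_len(n_prune)] else integer()
  kept <- sort(setdiff(seq_len(C), pruned))
  structure(list(layer_id = layer, kept = kept, C = C,
                 C_p = length(kept)), class = "prune_mask")
}

#' Select the channels to prune by threshold
#'
#' The comparison rule: channels with importance below
#' `TH = mu + sigma + k` are pruned, where `mu` and `sigma` are the mean and
#' standard deviation of the layer's importance vector and `k` is an
#' adjustable offset in `[0.1, 0.5]`.  At least one channel (the most
#' important; ties to the lowest index) is always kept.
#'
#' @param imp a `channel_importance` or numeric vector.
#' @param k threshold offset in `[0.1, 0.5]`.
#' @return a `prune_mask`.
#' @export
select_by_threshold <- function(imp, k) {
  if (k < 0.1 || k > 0.5) stop("k must lie in [0.1, 0.5]")
  w <- if (inherits(imp, "channel_importance")) imp$w else as.numeric(imp)
  layer <- if (inherits(imp, "channel_importance")) imp$layer_id else NA_character_
  C <- length(w)
  mu <- mean(w)
  sg <- if (C > 1) sqrt(mean((w - mu)^2)) else 0
  th <- mu + sg + k
  kept <- which(w >= th)
  if (!length(kept)) kept <- which.max(w)
  structure(list(layer_id = layer, kept = sort(kept), C = C,
                 C_p = length(kept)), class = "prune_mask")
}

#' @export
print.prune_mask <- function(x, ...) {
  cat(sprintf("prune mask [%s]: keep %d / %d channels\n",
              x$layer_id, x$C_p, x$C))
  invisible(x)
}

# ---- mask selection with residual coupling ---------------------------------

#' Select per-layer masks for one pruning loop
#'
#' Applies [select_prune_set()] independently per SEP layer, except that
#' layers coupled by an identity residual shortcut (both endpoints of an
#' elementwise addition with no projection) receive a common mask computed
#' from the mean of their importance vectors.
#'
#' @param model a `sep_model`.
#' @param importance result of [accumulate_importance()].
#' @param X per-loop proportion.
#' @return named list of `prune_mask`, keyed by module name.
#' @export
select_masks <- function(model, importance, X) {
  masks <- lapply(importance, function(imp) select_prune_set(imp, X))
  for (cp in model$couples) {
    a <- cp[1]; b <- cp[2]
    if (!all(c(a, b) %in% names(importance))) next
    wm <- (importance[[a]]$w + importance[[b]]$w) / 2
    shared <- select_prune_set(wm, X)
    for (nm in c(a, b)) {
      masks[[nm]]$kept <- shared$kept
      masks[[nm]]$C_p <- shared$C_p
    }
  }
  masks
}

# ---- physical surgery ------------------------------------------------------

# Slice the input-channel dimension of a conv weight matrix
# ((k*k*Cin) x Cout, row order ki + k*kj + k*k*(c-1)).
.slice_conv_input <- function(W, k, cin, kept) {
  rows <- as.numeric(outer(seq_len(k * k), (kept - 1) * k * k, `+`))
  W[rows, , drop = FALSE]
}

# Partition kept concat-space indices by branch; returns per-branch local
# kept indices (list named by branch).
.kept_by_branch <- function(branches, kept) {
  widths <- unlist(branches[c("b1", "b3", "b5", "pp")])
  out <- list()
  off <- 0L
  for (nm in names(widths)) {
    w <- widths[[nm]]
    local <- kept[kept > off & kept <= off + w] - off
    out[[nm]] <- local
    off <- off + w
  }
  out
}

#' Physically remove pruned channels from a model
#'
#' Applies per-layer [prune_mask]s as structural surgery: the producing
#' filters of pruned channels are removed from the owning Inception branch's
#' final convolution (and its BN), consuming layers' input weights are
#' sliced accordingly (including residual projections and the classifier),
#' and the SEP FC grids are sliced to the kept channel set with the
#' bottleneck recomputed as `max(1, round(C_p / r))`.  A branch whose
#' channels are all pruned is dropped structurally (together with its
#' reducer).  Only SEP-equipped Inception outputs are prunable; the three
#' stem convolutions are not.
#'
#' @param model a `sep_model`.
#' @param masks named list of `prune_mask` keyed by module name
#'   (e.g. `"3a"`), as from [select_masks()].
#' @return a new, structurally smaller `sep_model`.
#' @export
apply_pruning <- function(model, masks) {
  arch <- model$arch
  mod_names <- vapply(arch$modules, `[[`, "", "name")
  bad <- setdiff(names(masks), mod_names)
  if (length(bad))
    stop("mask(s) on non-prunable layer(s): ", paste(bad, collapse = ", "),
         " (only SEP-equipped Inception modules can be pruned)")
  # identity-coupled endpoints must receive identical masks
  for (cp in model$couples) {
    if (all(cp %in% names(masks)) &&
        !identical(masks[[cp[1]]]$kept, masks[[cp[2]]]$kept))
      stop("modules ", cp[1], " and ", cp[2],
           " share an identity shortcut and need a common mask")
  }

  params <- model$params
  state <- model$state
  new_arch <- arch

  slice_bn <- function(id, kept) {
    for (slot in c(".gamma", ".beta"))
      params[[paste0(id, slot)]] <<- params[[paste0(id, slot)]][kept]
    for (slot in c(".rmean", ".rvar"))
      state[[paste0(id, slot)]] <<- state[[paste0(id, slot)]][kept]
  }

  for (mi in seq_along(arch$modules)) {
    m <- arch$modules[[mi]]
    msk <- masks[[m$name]]
    if (is.null(msk)) next
    C <- .module_out_channels(m)
    if (msk$C != C)
      stop("mask for module ", m$name, " has C = ", msk$C,
           " but the module outputs ", C, " channels")
    kept <- msk$kept
    pre <- paste0("m", m$name)
    local <- .kept_by_branch(m$branches, kept)

    # producing filters: slice output columns of each branch-final conv
    bmap <- c(b1 = "b1", b3 = "b3", b5 = "b5", pp = "pp")
    for (bn in names(bmap)) {
      if (m$branches[[bn]] == 0) next
      keep_b <- local[[bn]]
      cid <- paste0(pre, ".", bn)
      if (length(keep_b) == 0) {
        # drop the whole branch (and its reducer)
        params[[paste0(cid, ".conv.W")]] <- NULL
        params[[paste0(cid, ".bn.gamma")]] <- NULL
        params[[paste0(cid, ".bn.beta")]] <- NULL
        state[[paste0(cid, ".bn.rmean")]] <- NULL
        state[[paste0(cid, ".bn.rvar")]] <- NULL
        red <- paste0(pre, ".", bn, "r")
        if (bn %in% c("b3", "b5")) {
          params[[paste0(red, ".conv.W")]] <- NULL
          params[[paste0(red, ".bn.gamma")]] <- NULL
          params[[paste0(red, ".bn.beta")]] <- NULL
          state[[paste0(red, ".bn.rmean")]] <- NULL
          state[[paste0(red, ".bn.rvar")]] <- NULL
          new_arch$modules[[mi]]$branches[[paste0(bn, "r")]] <- 0L
        }
        new_arch$modules[[mi]]$branches[[bn]] <- 0L
      } else {
        W <- params[[paste0(cid, ".conv.W")]]
        params[[paste0(cid, ".conv.W")]] <- W[, keep_b, drop = FALSE]
        slice_bn(paste0(cid, ".bn"), keep_b)
        new_arch$modules[[mi]]$branches[[bn]] <- length(keep_b)
      }
    }

    # SEP FC grids: columns/rows by kept set, bottleneck resized
    b_new <- .se_bottleneck(length(kept), arch$se_r)
    W1 <- params[[paste0(pre, ".sep.W1")]]
    W2 <- params[[paste0(pre, ".sep.W2")]]
    b_new <- min(b_new, nrow(W1))
    params[[paste0(pre, ".sep.W1")]] <- W1[seq_len(b_new), kept, drop = FALSE]
    params[[paste0(pre, ".sep.W2")]] <- W2[kept, seq_len(b_new), drop = FALSE]

    # consumers: next module's 1x1 entries, or the classifier
    if (mi < length(arch$modules)) {
      nxt <- arch$modules[[mi + 1L]]
      npre <- paste0("m", nxt$name)
      for (bn in c("b1", "b3r", "b5r", "pp")) {
        if (nxt$branches[[bn]] == 0) next
        key <- paste0(npre, ".", bn, ".conv.W")
        params[[key]] <- .slice_conv_input(params[[key]], 1L, C, kept)
      }
    } else {
      key <- "head.fc.W"
      params[[key]] <- params[[key]][, kept, drop = FALSE]
    }

    # residual projections touching this module's channel space
    for (lk in arch$residual_links %||% list()) {
      suffix <- if (lk$point == "input") "i" else "o"
      rid <- paste0("res.", lk$src, "to", lk$dst, suffix, ".proj.W")
      if (is.null(params[[rid]])) next
      if (lk$src == m$name)
        params[[rid]] <- .slice_conv_input(params[[rid]], 1L, C, kept)
      # destination space: module before dst for "input", dst for "output"
      dst_space <- if (lk$point == "output") lk$dst else {
        di <- which(mod_names == lk$dst)
        mod_names[di - 1L]
      }
      if (dst_space == m$name)
        params[[rid]] <- params[[rid]][, kept, drop = FALSE]
    }
  }

  # rebuild the graph against the pruned architecture
  g <- compile_graph(new_arch)
  structure(list(arch = new_arch, nodes = g$nodes, out_id = g$out_id,
                 couples = g$couples, params = params, state = state),
            class = "sep_model")
}

# ---- the prune-retrain loop ------------------------------------------------

#' Iterative prune-retrain loop
#'
#' Repeats `schedule$R` times: accumulate dataset-level channel importance,
#' select the per-layer `X` proportion of lowest-importance channels,
#' physically prune them, and retrain the compressed model (fine-tuning at
#' one tenth of the configured learning rate).  Records per-loop, per-layer
#' channel counts before and after surgery.
#'
#' @param model a pretrained `sep_model`.
#' @param train_data list with `x` (tensor or image list) and `y` (1-based
#'   integer labels), as for [train_branch()].
#' @param schedule a [prune_schedule()].
#' @param train_cfg a [train_config()] used for the retraining stages.
#' @return list with the compressed `model` and a `report` data frame
#'   (loop, layer, channels before/after).
#' @export
prune_retrain_loop <- function(model, train_data, schedule, train_cfg) {
  stopifnot(inherits(schedule, "prune_schedule"))
  report <- list()
  for (loop in seq_len(schedule$R)) {
    imp <- accumulate_importance(model, train_data$x)
    masks <- select_masks(model, imp, schedule$X)
    before <- vapply(masks, `[[`, 0L, "C")
    model <- apply_pruning(model, masks)
    after <- vapply(masks, `[[`, 0L, "C_p")
    report[[loop]] <- data.frame(loop = loop, layer = names(masks),
                                 channels_before = as.integer(before),
                                 channels_after = as.integer(after),
                                 row.names = NULL)
    ft_cfg <- train_cfg
    ft_cfg$initial_lr <- train_cfg$initial_lr * 0.1
    tr <- train_branch(model, train_data, ft_cfg)
    model <- tr$model
  }
  list(model = model, report = do.call(rbind, report))
}
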