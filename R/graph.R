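# Graph compilation and execution.  A model is a list:
#   arch   - the structured architecture (see architecture.R)
#   nodes  - ordered (topological) list of primitive nodes
#   params - named list of trainable arrays, keyed "<node id>.<slot>"
#   state  - named list of batch-norm running statistics
# Node fields: id, op, inputs (character vector of producer ids), plus
# op-specific geometry (k, stride, pad, ceil).

.node <- function(id, op, inputs, ...) {
  c(list(id = id, op = op, inputs = inputs), list(...))
}

# ---- compilation -----------------------------------------------------------

# Compile a conv+bn+relu block; returns final node id.
.emit_cbr <- function(nodes, id, input, k, stride, pad) {
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node(paste0(id, ".conv"), "conv", input, k = k, stride = stride,
          pad = pad)
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node(paste0(id, ".bn"), "bn", paste0(id, ".conv"))
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node(paste0(id, ".relu"), "relu", paste0(id, ".bn"))
  paste0(id, ".relu")
}

#' @keywords internal
compile_graph <- function(arch) {
  nodes <- new.env()
  nodes$lst <- list(.node("input", "input", character()))
  cur <- "input"
  cur_mod <- NULL                 # module name owning the current channels
  couples <- list()

  # stem: conv7x7/2 -> maxpool3/2 -> conv1x1 -> conv3x3 -> maxpool3/2
  cur <- .emit_cbr(nodes, "stem.c1", cur, k = 7L, stride = 2L, pad = 3L)
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node("stem.pool1", "maxpool", cur, k = 3L, stride = 2L, pad = 0L,
          ceil = TRUE)
  cur <- "stem.pool1"
  cur <- .emit_cbr(nodes, "stem.c2r", cur, k = 1L, stride = 1L, pad = 0L)
  cur <- .emit_cbr(nodes, "stem.c2", cur, k = 3L, stride = 1L, pad = 1L)
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node("stem.pool2", "maxpool", cur, k = 3L, stride = 2L, pad = 0L,
          ceil = TRUE)
  cur <- "stem.pool2"

  mod_channels <- function(m) sum(unlist(m$branches)[c("b1", "b3", "b5", "pp")])
  links <- arch$residual_links %||% list()

  for (m in arch$modules) {
    pre <- paste0("m", m$name)
    if (isTRUE(m$pool_before)) {
      nodes$lst[[length(nodes$lst) + 1L]] <-
        .node(paste0(pre, ".pool"), "maxpool", cur, k = 3L, stride = 2L,
              pad = 0L, ceil = TRUE)
      cur <- paste0(pre, ".pool")
    }
    # residual links landing at this module's input
    for (lk in links) {
      if (lk$dst != m$name || lk$point != "input") next
      src_out <- paste0("m", lk$src, ".sep")
      src_mod <- arch$modules[[which(vapply(arch$modules, `[[`, "", "name") == lk$src)]]
      src_c <- mod_channels(src_mod)
      dst_c <- if (is.null(cur_mod)) arch$stem$c2 else
        mod_channels(arch$modules[[which(vapply(arch$modules, `[[`, "", "name") == cur_mod)]])
      rid <- paste0("res.", lk$src, "to", lk$dst, "i")
      if (src_c != dst_c) {
        nodes$lst[[length(nodes$lst) + 1L]] <-
          .node(paste0(rid, ".proj"), "conv", src_out, k = 1L, stride = 1L,
                pad = 0L)
        src_out <- paste0(rid, ".proj")
      } else if (!is.null(cur_mod)) {
        couples[[length(couples) + 1L]] <- c(lk$src, cur_mod)
      }
      nodes$lst[[length(nodes$lst) + 1L]] <-
        .node(paste0(rid, ".add"), "add", c(cur, src_out))
      cur <- paste0(rid, ".add")
    }
    # inception branches
    b <- m$branches
    outs <- character()
    if (b$b1 > 0)
      outs <- c(outs, .emit_cbr(nodes, paste0(pre, ".b1"), cur, 1L, 1L, 0L))
    if (b$b3 > 0) {
      t3 <- .emit_cbr(nodes, paste0(pre, ".b3r"), cur, 1L, 1L, 0L)
      outs <- c(outs, .emit_cbr(nodes, paste0(pre, ".b3"), t3, 3L, 1L, 1L))
    }
    if (b$b5 > 0) {
      t5 <- .emit_cbr(nodes, paste0(pre, ".b5r"), cur, 1L, 1L, 0L)
      outs <- c(outs, .emit_cbr(nodes, paste0(pre, ".b5"), t5, 5L, 1L, 2L))
    }
    if (b$pp > 0) {
      nodes$lst[[length(nodes$lst) + 1L]] <-
        .node(paste0(pre, ".pp.pool"), "maxpool", cur, k = 3L, stride = 1L,
              pad = 1L, ceil = FALSE)
      outs <- c(outs, .emit_cbr(nodes, paste0(pre, ".pp"),
                                paste0(pre, ".pp.pool"), 1L, 1L, 0L))
    }
    nodes$lst[[length(nodes$lst) + 1L]] <-
      .node(paste0(pre, ".concat"), "concat", outs)
    nodes$lst[[length(nodes$lst) + 1L]] <-
      .node(paste0(pre, ".sep"), "se", paste0(pre, ".concat"))
    cur <- paste0(pre, ".sep")
    cur_mod <- m$name
    # residual links landing at this module's output
    for (lk in links) {
      if (lk$dst != m$name || lk$point != "output") next
      src_out <- paste0("m", lk$src, ".sep")
      src_mod <- arch$modules[[which(vapply(arch$modules, `[[`, "", "name") == lk$src)]]
      src_c <- mod_channels(src_mod)
      dst_c <- mod_channels(m)
      rid <- paste0("res.", lk$src, "to", lk$dst, "o")
      if (src_c != dst_c) {
        nodes$lst[[length(nodes$lst) + 1L]] <-
          .node(paste0(rid, ".proj"), "conv", src_out, k = 1L, stride = 1L,
                pad = 0L)
        src_out <- paste0(rid, ".proj")
      } else {
        couples[[length(couples) + 1L]] <- c(lk$src, m$name)
      }
      nodes$lst[[length(nodes$lst) + 1L]] <-
        .node(paste0(rid, ".add"), "add", c(cur, src_out))
      cur <- paste0(rid, ".add")
    }
  }

  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node("head.pool", "maxpool", cur, k = 3L, stride = 2L, pad = 0L,
          ceil = TRUE)
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node("head.gap", "gap", "head.pool")
  nodes$lst[[length(nodes$lst) + 1L]] <-
    .node("head.fc", "fc", "head.gap")
  list(nodes = nodes$lst, out_id = "head.fc", couples = couples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- execution -------------------------------------------------------------

#' Forward pass through a model graph
#'
#' @param model a `sep_model`.
#' @param x input tensor `(H, W, N, C)` (see [stack_images()]).
#' @param train use batch statistics and update running BN state.
#' @param want_cache keep the per-node caches needed for a backward pass.
#' @param capture_se also return the per-sample SE activation factors `s`
#'   (an `N x C` matrix per SEP block), used for importance accumulation.
#' @return list with `out` (logits, `N x n_classes`), `vals`, `caches`,
#'   `state`, `se`, `shapes`.
#' @keywords internal
forward_graph <- function(model, x, train = FALSE, want_cache = FALSE,
                          capture_se = FALSE, bn_momentum = 0.9) {
  vals <- list(input = x)
  caches <- list()
  se <- list()
  shapes <- list(input = dim(x))
  state <- model$state
  p <- model$params
  for (nd in model$nodes) {
    if (nd$op == "input") next
    id <- nd$id
    out <- switch(nd$op,
      conv = {
        r <- conv_fw(vals[[nd$inputs]], p[[paste0(id, ".W")]], nd$k,
                     nd$stride, nd$pad, cache = want_cache)
        if (want_cache) caches[[id]] <- r[c("P", "in_dims")]
        r$out
      },
      bn = {
        r <- bn_fw(vals[[nd$inputs]], p[[paste0(id, ".gamma")]],
                   p[[paste0(id, ".beta")]], state[[paste0(id, ".rmean")]],
                   state[[paste0(id, ".rvar")]], momentum = bn_momentum,
                   train = train, cache = want_cache)
        if (train) {
          state[[paste0(id, ".rmean")]] <- r$rmean
          state[[paste0(id, ".rvar")]] <- r$rvar
        }
        if (want_cache) caches[[id]] <- r[c("xhat", "istd", "dims")]
        r$out
      },
      relu = relu_fw(vals[[nd$inputs]]),
      maxpool = {
        r <- maxpool_fw(vals[[nd$inputs]], nd$k, nd$stride, nd$pad, nd$ceil)
        if (want_cache) caches[[id]] <- r[c("argmax", "in_dims")]
        r$out
      },
      gap = {
        r <- gap_fw(vals[[nd$inputs]])
        if (want_cache) caches[[id]] <- r["in_dims"]
        r$out
      },
      se = {
        r <- se_fw(vals[[nd$inputs]], p[[paste0(id, ".W1")]],
                   p[[paste0(id, ".W2")]], cache = want_cache)
        if (want_cache) caches[[id]] <- r[c("z", "a", "h", "s", "x", "dims")]
        if (capture_se) se[[id]] <- r$s
        r$out
      },
      concat = {
        ins <- lapply(nd$inputs, function(i) vals[[i]])
        dims <- lapply(ins, dim)
        ctot <- sum(vapply(dims, `[`, 0, 4L))
        d1 <- dims[[1]]
        out <- array(0, c(d1[1], d1[2], d1[3], ctot))
        off <- 0L
        for (a in ins) {
          ca <- dim(a)[4]
          out[, , , (off + 1):(off + ca)] <- a
          off <- off + ca
        }
        if (want_cache)
          caches[[id]] <- list(widths = vapply(dims, `[`, 0L, 4L))
        out
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      fc = fc_fw(vals[[nd$inputs]], p[[paste0(id, ".W")]],
                 p[[paste0(id, ".b")]]),
      stop("unknown op: ", nd$op)
    )
    vals[[id]] <- out
    shapes[[id]] <- dim(out)
  }
  list(out = vals[[model$out_id]], vals = vals, caches = caches,
       state = state, se = se, shapes = shapes)
}

#' Backward pass; returns parameter gradients
#' @keywords internal
backward_graph <- function(model, fw, dout) {
  grads <- list()
  dmap <- list()
  dmap[[model$out_id]] <- dout
  vals <- fw$vals
  caches <- fw$caches
  p <- model$params
  acc <- function(id, g) {
    dmap[[id]] <<- if (is.null(dmap[[id]])) g else dmap[[id]] + g
  }
  for (nd in rev(model$nodes)) {
    if (nd$op == "input") next
    dY <- dmap[[nd$id]]
    if (is.null(dY)) next
    id <- nd$id
    switch(nd$op,
      conv = {
        r <- conv_bw(dY, caches[[id]], p[[paste0(id, ".W")]], nd$k,
                     nd$stride, nd$pad)
        grads[[paste0(id, ".W")]] <- r$dW
        acc(nd$inputs, r$dx)
      },
      bn = {
        r <- bn_bw(dY, caches[[id]], p[[paste0(id, ".gamma")]])
        grads[[paste0(id, ".gamma")]] <- r$dgamma
        grads[[paste0(id, ".beta")]] <- r$dbeta
        acc(nd$inputs, r$dx)
      },
      relu = acc(nd$inputs, relu_bw(dY, vals[[nd$inputs]])),
      maxpool = acc(nd$inputs, maxpool_bw(dY, caches[[id]])),
      gap = acc(nd$inputs, gap_bw(dY, caches[[id]])),
      se = {
        r <- se_bw(dY, caches[[id]], p[[paste0(id, ".W1")]],
                   p[[paste0(id, ".W2")]])
        grads[[paste0(id, ".W1")]] <- r$dW1
        grads[[paste0(id, ".W2")]] <- r$dW2
        acc(nd$inputs, r$dx)
      },
      concat = {
        off <- 0L
        for (j in seq_along(nd$inputs)) {
          cw <- caches[[id]]$widths[j]
          acc(nd$inputs[j], dY[, , , (off + 1):(off + cw), drop = FALSE])
          off <- off + cw
        }
      },
      add = {
        acc(nd$inputs[1], dY)
        acc(nd$inputs[2], dY)
      },
      fc = {
        r <- fc_bw(dY, vals[[nd$inputs]], p[[paste0(id, ".W")]])
        grads[[paste0(id, ".W")]] <- r$dW
        grads[[paste0(id, ".b")]] <- r$db
        acc(nd$inputs, r$dx)
      }
    )
    dmap[[id]] <- NULL
  }
  grads
}
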