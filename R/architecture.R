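# Architecture builder: the 7-Inception / SEP-block two-branch CNN, its
# width-scaled desk profiles, parameter initialization, and weight / FLOP
# counters.

# Canonical GoogLeNet branch allocations for modules 3a-4d; their totals
# equal the published per-module output widths (256, 480, 512, 512, 512,
# 528).  Module 4e totals 1856 output channels, which the canonical
# allocation (832) does not reach; its four branches are scaled
# proportionally (largest-remainder rounding) to that total, with the two
# reducers scaled by the same ratio.  See inst/extdata/inception_allocations.yaml.
.INCEPTION_CANON <- list(
  list(name = "3a", pool_before = FALSE,
       branches = list(b1 = 64, b3r = 96, b3 = 128, b5r = 16, b5 = 32, pp = 32)),
  list(name = "3b", pool_before = FALSE,
       branches = list(b1 = 128, b3r = 128, b3 = 192, b5r = 32, b5 = 96, pp = 64)),
  list(name = "4a", pool_before = TRUE,
       branches = list(b1 = 192, b3r = 96, b3 = 208, b5r = 16, b5 = 48, pp = 64)),
  list(name = "4b", pool_before = FALSE,
       branches = list(b1 = 160, b3r = 112, b3 = 224, b5r = 24, b5 = 64, pp = 64)),
  list(name = "4c", pool_before = FALSE,
       branches = list(b1 = 128, b3r = 128, b3 = 256, b5r = 24, b5 = 64, pp = 64)),
  list(name = "4d", pool_before = FALSE,
       branches = list(b1 = 112, b3r = 144, b3 = 288, b5r = 32, b5 = 64, pp = 64)),
  list(name = "4e", pool_before = FALSE,
       branches = list(b1 = 256, b3r = 160, b3 = 320, b5r = 32, b5 = 128, pp = 128))
)
.MODULE_TOTALS <- c("3a" = 256, "3b" = 480, "4a" = 512, "4b" = 512,
                    "4c" = 512, "4d" = 528, "4e" = 1856)

round_half_up <- function(x) floor(x + 0.5)

# Scale integer weights proportionally so they sum to `total`
# (largest-remainder rounding; ties broken by position).
scale_to_total <- function(weights, total) {
  raw <- weights * total / sum(weights)
  fl <- floor(raw)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Architecture specification of the two-branch CNN
#'
#' Builds the structured description of the network of the initial model:
#' a convolutional stem (7x7/2 conv, max pool, 1x1 conv, 3x3 conv, max
#' pool), seven Inception modules (3a, 3b, 4a-4e) each followed by a SEP
#' block, two residual shortcuts (4c to the input of 4e, 4d to the output of
#' SEP-4e, with 1x1 projections when channel counts differ), and a head of
#' max pool, global average pool and a 2-way linear classifier.
#'
#' `width_multiplier` scales every channel count (floor 1) for desk-scale
#' models; the default toy profile is `width_multiplier = 1/8` with 64-pixel
#' inputs.
#'
#' @param width_multiplier channel scale factor in `(0, 1]`.
#' @param input_side input image side in pixels (default 224).
#' @param n_classes output classes (default 2).
#' @param se_r SE bottleneck reduction ratio (default 16).
#' @param n_modules use only the first `n_modules` Inception modules
#'   (default all 7); residual links whose endpoints are absent are dropped.
#' @return object of class `sep_arch`.
#' @export
network_architecture <- function(width_multiplier = 1, input_side = 224L,
                                 n_classes = 2L, se_r = 16L,
                                 n_modules = 7L) {
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must lie in (0, 1]")
  scale_w <- function(w) max(1L, as.integer(round_half_up(w * width_multiplier)))
  mods <- .INCEPTION_CANON[seq_len(n_modules)]
  mods <- lapply(mods, function(m) {
    target <- .MODULE_TOTALS[[m$name]]
    outs <- unlist(m$branches[c("b1", "b3", "b5", "pp")])
    if (sum(outs) != target) {
      ratio <- target / sum(outs)
      outs <- scale_to_total(outs, target)
      m$branches$b3r <- as.integer(round_half_up(m$branches$b3r * ratio))
      m$branches$b5r <- as.integer(round_half_up(m$branches$b5r * ratio))
      m$branches[c("b1", "b3", "b5", "pp")] <- as.list(outs)
    }
    m$branches <- lapply(m$branches, scale_w)
    m
  })
  links <- list()
  have <- vapply(mods, `[[`, "", "name")
  if (all(c("4c", "4e") %in% have))
    links[[length(links) + 1L]] <- list(src = "4c", dst = "4e", point = "input")
  if (all(c("4d", "4e") %in% have))
    links[[length(links) + 1L]] <- list(src = "4d", dst = "4e", point = "output")
  structure(list(
    input_side = as.integer(input_side), in_channels = 3L,
    n_classes = as.integer(n_classes), se_r = as.integer(se_r),
    width_multiplier = width_multiplier,
    stem = list(c1 = scale_w(64), c2r = scale_w(64), c2 = scale_w(192)),
    modules = mods, residual_links = links
  ), class = "sep_arch")
}

#' Desk-scale toy architecture (1/8 widths, 64-pixel inputs)
#' @param input_side input side in pixels (default 64).
#' @param width_multiplier channel scale (default 1/8).
#' @param ... forwarded to [network_architecture()].
#' @export
toy_architecture <- function(input_side = 64L, width_multiplier = 1 / 8, ...) {
  network_architecture(width_multiplier = width_multiplier,
                       input_side = input_side, ...)
}

#' Save / load an architecture spec as YAML
#'
#' @param arch a `sep_arch`.
#' @param path YAML file path.
#' @export
save_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "sep_arch"))
  yaml::write_yaml(unclass(arch), path, precision = 15L)
  invisible(path)
}

#' @rdname save_architecture
#' @export
load_architecture <- function(path) {
  v <- yaml::read_yaml(path)
  if (is.null(v$modules) || is.null(v$stem))
    stop("not an architecture YAML file: ", path)
  v$input_side <- as.integer(v$input_side)
  v$in_channels <- as.integer(v$in_channels)
  v$n_classes <- as.integer(v$n_classes)
  v$se_r <- as.integer(v$se_r)
  v$stem <- lapply(v$stem, as.integer)
  v$modules <- lapply(v$modules, function(m) {
    m$branches <- lapply(m$branches, as.integer)
    m
  })
  structure(v, class = "sep_arch")
}

#' @export
print.sep_arch <- function(x, ...) {
  cat(sprintf("sep_arch: input %dpx, width x%.3g, %d Inception+SEP modules, %d classes\n",
              x$input_side, x$width_multiplier, length(x$modules),
              x$n_classes))
  for (m in x$modules)
    cat(sprintf("  %s%s: %s -> %d channels\n", m$name,
                if (m$pool_before) " (pool)" else "",
                paste(sprintf("%s=%d", names(m$branches),
                              unlist(m$branches)), collapse = " "),
                sum(unlist(m$branches)[c("b1", "b3", "b5", "pp")])))
  invisible(x)
}

.module_out_channels <- function(m)
  sum(unlist(m$branches)[c("b1", "b3", "b5", "pp")])

.se_bottleneck <- function(C, r) max(1L, as.integer(round_half_up(C / r)))

# He-style init for a conv weight matrix (k*k*Cin) x Cout.
.init_conv <- function(k, cin, cout)
  matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
         k * k * cin, cout)

#' Build a model from an architecture spec
#'
#' Instantiates one branch of the hybrid network: compiles the architecture
#' into a primitive-op graph and draws He-initialized weights.  The global
#' and local branches are two independent instances of the same spec.
#'
#' @param arch a [network_architecture()] spec.
#' @param seed RNG seed for the weight draw.
#' @return object of class `sep_model`.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "sep_arch"))
  g <- compile_graph(arch)
  set.seed(seed)
  params <- list()
  state <- list()
  # channel bookkeeping per node id
  chan <- c(input = arch$in_channels)
  for (nd in g$nodes) {
    id <- nd$id
    switch(nd$op,
      input = NULL,
      conv = {
        cin <- chan[[nd$inputs]]
        cout <- .conv_out_channels(arch, id, cin)
        params[[paste0(id, ".W")]] <- .init_conv(nd$k, cin, cout)
        chan[[id]] <- cout
      },
      bn = {
        c0 <- chan[[nd$inputs]]
        params[[paste0(id, ".gamma")]] <- rep(1, c0)
        params[[paste0(id, ".beta")]] <- rep(0, c0)
        state[[paste0(id, ".rmean")]] <- rep(0, c0)
        state[[paste0(id, ".rvar")]] <- rep(1, c0)
        chan[[id]] <- c0
      },
      se = {
        c0 <- chan[[nd$inputs]]
        b <- .se_bottleneck(c0, arch$se_r)
        params[[paste0(id, ".W1")]] <- matrix(rnorm(b * c0, 0, sqrt(2 / c0)),
                                              b, c0)
        params[[paste0(id, ".W2")]] <- matrix(rnorm(c0 * b, 0, sqrt(1 / b)),
                                              c0, b)
        chan[[id]] <- c0
      },
      concat = chan[[id]] <- sum(vapply(nd$inputs, function(i) chan[[i]], 0)),
      add = chan[[id]] <- chan[[nd$inputs[1]]],
      fc = {
        c0 <- chan[[nd$inputs]]
        params[[paste0(id, ".W")]] <- matrix(rnorm(arch$n_classes * c0, 0,
                                                   sqrt(2 / c0)),
                                             arch$n_classes, c0)
        params[[paste0(id, ".b")]] <- rep(0, arch$n_classes)
        chan[[id]] <- arch$n_classes
      },
      chan[[id]] <- chan[[nd$inputs[1]]]   # relu, maxpool, gap
    )
  }
  structure(list(arch = arch, nodes = g$nodes, out_id = g$out_id,
                 couples = g$couples, params = params, state = state),
            class = "sep_model")
}

# Output channel count for a conv node id, derived from the arch.
.conv_out_channels <- function(arch, id, cin) {
  if (id == "stem.c1.conv") return(arch$stem$c1)
  if (id == "stem.c2r.conv") return(arch$stem$c2r)
  if (id == "stem.c2.conv") return(arch$stem$c2)
  if (grepl("^res\\.", id)) {
    # projection: out channels = channels of the destination space
    base <- sub("^res\\.", "", sub("\\.proj$", "", id))
    point <- substring(base, nchar(base))        # "i" or "o"
    pair <- strsplit(substring(base, 1, nchar(base) - 1), "to")[[1]]
    dst <- pair[2]
    idx <- which(vapply(arch$modules, `[[`, "", "name") == dst)
    if (point == "o")
      return(.module_out_channels(arch$modules[[idx]]))
    # input point: space of the predecessor module
    return(.module_out_channels(arch$modules[[idx - 1L]]))
  }
  m <- regmatches(id, regexec("^m([^.]+)\\.(b1|b3r|b3|b5r|b5|pp)\\.conv$", id))[[1]]
  if (length(m) == 3L) {
    idx <- which(vapply(arch$modules, `[[`, "", "name") == m[2])
    return(arch$modules[[idx]]$branches[[m[3]]])
  }
  stop("cannot determine output channels for conv node ", id)
}

#' @export
print.sep_model <- function(x, ...) {
  cp <- count_params_flops(x)
  cat(sprintf("sep_model: %d nodes, %s weights, %s FLOPs @ %dpx\n",
              length(x$nodes), format(cp[["weights"]], big.mark = ","),
              format(cp[["flops"]], big.mark = ","), x$arch$input_side))
  invisible(x)
}

#' Class-probability predictions of a single branch
#'
#' Runs the model in inference mode (BN running statistics) and applies the
#' softmax.
#'
#' @param model a `sep_model`.
#' @param x input tensor `(H, W, N, 3)`, a single `H x W x 3` image, or a
#'   list of images.
#' @return `N x n_classes` matrix of probabilities, rows summing to 1.
#' @export
predict_model <- function(model, x) {
  x <- as_batch(x)
  softmax_rows(forward_graph(model, x)$out)
}

#' @keywords internal
as_batch <- function(x) {
  if (is.list(x)) return(stack_images(x))
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    return(array(x, c(d[1], d[2], 1L, d[3])))
  }
  x
}

#' Audit per-module output shapes
#'
#' Runs a dummy forward pass and reports the output shape of the stem
#' stages, every Inception module (after its SEP block), and the head —
#' the desk check that the instantiated network matches its published
#' layer table.
#'
#' @param model a `sep_model`.
#' @return data frame with columns `node`, `H`, `W`, `C`.
#' @export
architecture_audit <- function(model) {
  side <- model$arch$input_side
  x <- array(0, c(side, side, 1L, model$arch$in_channels))
  shapes <- forward_graph(model, x)$shapes
  keep <- c("stem.c1.conv", "stem.pool1", "stem.c2r.conv", "stem.c2.conv",
            "stem.pool2",
            unlist(lapply(model$arch$modules, function(m)
              c(if (m$pool_before) paste0("m", m$name, ".pool"),
                paste0("m", m$name, ".sep")))),
            "head.pool", "head.gap", "head.fc")
  keep <- intersect(keep, names(shapes))
  rows <- lapply(keep, function(id) {
    d <- shapes[[id]]
    if (length(d) == 4L)
      data.frame(node = id, H = d[1], W = d[2], C = d[4])
    else
      data.frame(node = id, H = 1L, W = 1L, C = d[2])
  })
  do.call(rbind, rows)
}

#' Count trainable weights and forward FLOPs
#'
#' Weights are all trainable scalars (convolution and FC weights, SE
#' weights, BN scale/shift; BN running statistics are excluded).  FLOPs are
#' counted as 2 x multiply-accumulates of the convolution and linear layers
#' for one input image; pooling, BN and the SE gating are not counted.
#'
#' @param model a `sep_model` (or a compatible hand-built node/param list).
#' @param input_side input side used for the FLOP count; defaults to the
#'   architecture's input side.
#' @return named numeric vector `c(weights = ..., flops = ...)`.
#' @export
count_params_flops <- function(model, input_side = NULL) {
  if (is.null(input_side)) input_side <- model$arch$input_side
  weights <- sum(vapply(model$params, length, 0))
  if (!length(model$nodes))
    return(c(weights = weights, flops = 0))
  in_ch <- model$arch$in_channels %||% 3L
  x <- array(0, c(input_side, input_side, 1L, in_ch))
  shapes <- forward_graph(model, x)$shapes
  flops <- 0
  for (nd in model$nodes) {
    if (nd$op == "conv") {
      W <- model$params[[paste0(nd$id, ".W")]]
      os <- shapes[[nd$id]]
      flops <- flops + 2 * nrow(W) * ncol(W) * os[1] * os[2]
    } else if (nd$op == "fc") {
      W <- model$params[[paste0(nd$id, ".W")]]
      flops <- flops + 2 * length(W)
    }
  }
  c(weights = weights, flops = flops)
}
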