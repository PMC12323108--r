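#' Loss configuration
#'
#' Weights of the Hungarian-matched mask-classification objective
#' \eqn{L = \alpha (L_{ce} + L_{dice}) + \beta L_{clas}}.
#'
#' @param alpha weight of the per-pixel mask loss (binary cross-entropy plus
#'   dice), default 0.7.
#' @param beta weight of the per-query classification cross-entropy,
#'   default 0.3.
#' @param no_object_weight down-weight of the no-object class for unmatched
#'   queries in the classification term.
#' @return A `loss_config` object.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, no_object_weight = 0.1) {
  stopifnot(alpha >= 0, beta >= 0, no_object_weight >= 0)
  structure(list(alpha = alpha, beta = beta, no_object_weight = no_object_weight),
            class = "loss_config")
}

#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation with row/column potentials.
#' Rows may not exceed columns; every row is assigned a distinct column.
#'
#' @param cost numeric cost matrix (`n x m`, `n <= m`).
#' @return List with `assignment` (column index per row) and `cost` (total).
#' @export
hungarian_solve <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  if (n > m) stop("cost matrix must have nrow <= ncol", call. = FALSE)
  u <- numeric(n)
  v <- numeric(m + 1L) # index j+1; slot 1 is the virtual column
  p <- integer(m + 1L) # row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}

#' Mask losses: binary cross-entropy and dice
#'
#' `L_ce` is the mean binary cross-entropy over pixels (probabilities clamped
#' to `[1e-7, 1 - 1e-7]`); `L_dice = 1 - (2*sum(p*g) + s) / (sum(p) + sum(g)
#' + s)` with smoothing `s = 1`.
#'
#' @param prob predicted mask probabilities (any shape).
#' @param gt congruent binary ground-truth mask.
#' @param smooth dice smoothing constant.
#' @return List with `l_ce` and `l_dice`.
#' @export
mask_losses <- function(prob, gt, smooth = 1) {
  if (!identical(dim(as.array(prob)), dim(as.array(gt))) &&
      length(prob) != length(gt))
    stop("prediction and ground truth must be congruent", call. = FALSE)
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  g <- as.numeric(gt > 0)
  l_ce <- -mean(g * log(p) + (1 - g) * log(1 - p))
  l_dice <- 1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
  list(l_ce = l_ce, l_dice = l_dice)
}

#' Match predicted queries to ground-truth instances
#'
#' Builds the matching cost `cost(q, g) = alpha * (ce + dice) + beta *
#' (-log p_q(class_g))` between every query's soft mask/class posterior and
#' every ground-truth instance, and solves the minimum-cost assignment with
#' [hungarian_solve()]. Queries left unmatched map to the no-object class.
#'
#' @param mask_prob per-query mask probabilities (`X x P`).
#' @param class_logits per-query class logits (`X x (C+1)`; the last column
#'   is the no-object slot).
#' @param instances list of ground-truth instances, each a list with `mask`
#'   (length-`P` binary) and `class` (1-based semantic class index).
#' @param config a [loss_config] (the matching cost reuses `alpha`/`beta`).
#' @return List with `pairs` (matrix: columns `target`, `query`),
#'   `unmatched_queries`, and the assignment `cost`.
#' @export
hungarian_match <- function(mask_prob, class_logits, instances,
                            config = loss_config()) {
  X <- nrow(mask_prob)
  G <- length(instances)
  if (G == 0L)
    return(list(pairs = cbind(target = integer(0), query = integer(0)),
                unmatched_queries = seq_len(X), cost = 0))
  if (G > X) stop("more ground-truth instances than queries", call. = FALSE)
  lp <- class_logits - apply(class_logits, 1L, max)
  logp <- lp - log(rowSums(exp(lp)))
  cost <- matrix(0, G, X)
  for (g in seq_len(G)) {
    tgt <- instances[[g]]
    for (q in seq_len(X)) {
      ml <- mask_losses(mask_prob[q, ], tgt$mask)
      cost[g, q] <- config$alpha * (ml$l_ce + ml$l_dice) -
        config$beta * logp[q, tgt$class]
    }
  }
  sol <- hungarian_solve(cost)
  pairs <- cbind(target = seq_len(G), query = sol$assignment)
  list(pairs = pairs,
       unmatched_queries = setdiff(seq_len(X), sol$assignment),
       cost = sol$cost)
}

#' Combine loss components
#'
#' `L = alpha * (l_ce + l_dice) + beta * l_clas`.
#'
#' @param l_ce,l_dice,l_clas loss components.
#' @param config a [loss_config].
#' @return Scalar total loss.
#' @export
combine_loss <- function(l_ce, l_dice, l_clas, config = loss_config()) {
  config$alpha * (l_ce + l_dice) + config$beta * l_clas
}

#' Total Hungarian-matched mask-classification loss
#'
#' Matches queries to ground-truth instances, averages the binary
#' cross-entropy and dice losses over the matched masks, computes the
#' classification cross-entropy over all queries (no-object target, weighted
#' by `no_object_weight`, for the unmatched ones), and combines them with
#' [combine_loss()].
#'
#' @inheritParams hungarian_match
#' @return List with `total`, `l_ce`, `l_dice`, `l_clas` and the `match`.
#' @export
total_loss <- function(mask_prob, class_logits, instances,
                       config = loss_config()) {
  X <- nrow(mask_prob)
  C1 <- ncol(class_logits)
  mt <- hungarian_match(mask_prob, class_logits, instances, config)
  l_ce <- 0; l_dice <- 0
  if (nrow(mt$pairs) > 0) {
    for (k in seq_len(nrow(mt$pairs))) {
      tgt <- instances[[mt$pairs[k, "target"]]]
      ml <- mask_losses(mask_prob[mt$pairs[k, "query"], ], tgt$mask)
      l_ce <- l_ce + ml$l_ce / nrow(mt$pairs)
      l_dice <- l_dice + ml$l_dice / nrow(mt$pairs)
    }
  }
  target <- rep(C1, X) # no-object slot
  weights <- rep(config$no_object_weight, X)
  if (nrow(mt$pairs) > 0) {
    target[mt$pairs[, "query"]] <-
      vapply(mt$pairs[, "target"], function(g) instances[[g]]$class, numeric(1))
    weights[mt$pairs[, "query"]] <- 1
  }
  lp <- class_logits - apply(class_logits, 1L, max)
  logp <- lp - log(rowSums(exp(lp)))
  ce_rows <- -logp[cbind(seq_len(X), target)]
  l_clas <- sum(weights * ce_rows) / sum(weights)
  list(total = combine_loss(l_ce, l_dice, l_clas, config),
       l_ce = l_ce, l_dice = l_dice, l_clas = l_clas, match = mt)
}
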