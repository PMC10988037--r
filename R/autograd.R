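#' @useDynLib vesselvnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- minimal reverse-mode autodiff tape -------------------------------------
#
# Each node is an environment holding a numeric array `value`, an accumulated
# `grad`, its `parents`, and a `backward` closure mapping the node's output
# gradient to a list of parent gradients (NULL entries are skipped). Graphs
# are small (one node per layer), so a DFS topological sort at backward time
# is cheap relative to the convolutions themselves.

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ag_state$counter <- .ag_state$counter + 1L
  e$id <- .ag_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- FALSE
  class(e) <- "ag_node"
  e
}

#' Create a trainable parameter node
#' @param value numeric array of initial values
#' @return an `ag_node` flagged as a parameter
#' @keywords internal
ag_param <- function(value) {
  n <- ag_node(value)
  n$is_param <- TRUE
  n
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_constant <- function(value) ag_node(value)

# topological order via iterative DFS
ag_topo <- function(root) {
  order <- vector("list", 64L)
  n_out <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$expanded) {
      n_out <- n_out + 1L
      if (n_out > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_out]] <- node
    } else if (is.null(visited[[key]])) {
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, expanded = TRUE)
      for (p in node$parents) {
        if (inherits(p, "ag_node") && is.null(visited[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  order[seq_len(n_out)]
}

#' Run reverse-mode accumulation from a scalar (or seeded) root node
#'
#' @param root output `ag_node`
#' @param seed gradient to seed at the root; defaults to 1 for scalar roots
#' @keywords internal
ag_backward <- function(root, seed = NULL) {
  order <- ag_topo(root)
  for (n in order) n$grad <- NULL
  if (is.null(seed)) {
    if (length(root$value) != 1L)
      stop("backward from a non-scalar node requires an explicit seed gradient")
    seed <- 1
  }
  root$grad <- seed
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      g <- grads[[j]]
      if (!inherits(p, "ag_node") || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# collect all parameter nodes reachable from a (possibly nested) list
ag_collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (inherits(v, "ag_node")) {
      if (v$is_param) out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}
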