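#' Back-door adjustment set for a causal effect
#'
#' Under the fitted DAG, the parents of the exposure block every back-door
#' path into it, so they form a valid adjustment set separating confounders
#' from mere covariates. When the outcome is not a descendant of the
#' exposure the causal effect is structurally zero, which is flagged.
#'
#' @param graph an acyclic trait graph.
#' @param exposure,outcome trait names, distinct.
#' @return list with `set` (character vector of parent names) and
#'   `structural_zero` (logical: outcome unreachable from exposure).
#' @export
adjustment_set <- function(graph, exposure, outcome) {
  nodes <- igraph::V(graph)$name
  missing <- setdiff(c(exposure, outcome), nodes)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  if (exposure == outcome) stop("exposure and outcome must differ")
  parents <- names(igraph::neighbors(graph, exposure, mode = "in"))
  list(set = sort(setdiff(parents, outcome)),
       structural_zero = !outcome %in% influence_set(graph, exposure))
}

#' Estimate a causal effect by linear back-door adjustment
#'
#' Least-squares coefficient of the exposure in the regression of the
#' outcome on the exposure and its adjustment set (parents of the exposure
#' in the fitted graph), with its standard error. On standardized traits the
#' estimate is in per-SD units. Structurally-zero pairs (outcome not
#' downstream of exposure) are still estimated but flagged.
#'
#' @param data samples x traits numeric matrix or data.frame; complete cases
#'   are used.
#' @param graph the fitted trait DAG.
#' @param exposure,outcome trait names.
#' @param estimand `"total"` (default) adjusts for the parents of the
#'   exposure, so the coefficient aggregates every directed path from
#'   exposure to outcome; `"direct"` adjusts for the other parents of the
#'   outcome, isolating the single-edge coefficient of the structural
#'   equation (zero when no edge exists).
#' @return one-row `data.frame` of class `effect_estimate` with columns
#'   `exposure`, `outcome`, `adjustment_set` (semicolon-joined), `estimate`,
#'   `se`, `n_used`, `structural_zero`.
#' @export
estimate_effect <- function(data, graph, exposure, outcome,
                            estimand = c("total", "direct")) {
  estimand <- match.arg(estimand)
  adj <- adjustment_set(graph, exposure, outcome)
  if (estimand == "direct") {
    pa_out <- names(igraph::neighbors(graph, outcome, mode = "in"))
    adj$set <- sort(setdiff(pa_out, exposure))
    adj$structural_zero <- !igraph::are_adjacent(graph, exposure, outcome)
  }
  data <- as.data.frame(data, check.names = FALSE)
  need <- c(outcome, exposure, adj$set)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("trait(s) absent from data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), need, drop = FALSE]
  X <- as.matrix(cbind(`(Intercept)` = 1, d[, c(exposure, adj$set), drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    involved <- setdiff(colnames(X)[-1L], NULL)
    stop("collinear adjustment covariates: ",
         paste(dropped, collapse = ", "),
         " linearly dependent on {", paste(setdiff(involved, dropped),
                                           collapse = ", "), "}")
  }
  fit <- stats::lm(d[[outcome]] ~ X - 1)
  sm <- summary(fit)$coefficients
  row <- match(paste0("X", exposure), rownames(sm))
  out <- data.frame(exposure = exposure, outcome = outcome,
                    adjustment_set = paste(adj$set, collapse = ";"),
                    estimate = unname(sm[row, 1L]),
                    se = unname(sm[row, 2L]),
                    n_used = nrow(d),
                    structural_zero = adj$structural_zero,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Estimate the effects of an exposure on its local (child) metabolites
#'
#' @inheritParams estimate_effect
#' @param exposure trait name; effects are estimated on every child.
#' @return `data.frame` of stacked [estimate_effect()] rows, one per child.
#' @export
estimate_child_effects <- function(data, graph, exposure,
                                   estimand = c("total", "direct")) {
  estimand <- match.arg(estimand)
  children <- sort(names(igraph::neighbors(graph, exposure, mode = "out")))
  out <- do.call(rbind, lapply(children, function(ch)
    estimate_effect(data, graph, exposure, ch, estimand = estimand)))
  out %||% empty_effect_table()
}

#' Residual standard deviation of each node's structural equation
#'
#' @inheritParams estimate_effect
#' @return named numeric vector over trait nodes.
#' @export
node_residual_sd <- function(data, graph) {
  data <- as.data.frame(data, check.names = FALSE)
  nodes <- igraph::V(graph)$name
  vapply(nodes, function(v) {
    pa <- names(igraph::neighbors(graph, v, mode = "in"))
    d <- data[stats::complete.cases(data[c(v, pa)]), , drop = FALSE]
    if (!length(pa)) return(stats::sd(d[[v]]))
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", pa),
                                        response = sprintf("`%s`", v)),
                     data = d)
    summary(fit)$sigma
  }, 0)
}

empty_effect_table <- function() {
  data.frame(exposure = character(), outcome = character(),
             adjustment_set = character(), estimate = numeric(),
             se = numeric(), n_used = integer(),
             structural_zero = logical(), stringsAsFactors = FALSE)
}

#' Effect table for every edge of the fitted graph
#'
#' One row per directed trait edge; the default `"direct"` estimand makes
#' the table the fitted structural-equation coefficients of the network.
#'
#' @inheritParams estimate_effect
#' @return `data.frame`, one row per directed trait edge.
#' @export
estimate_all_effects <- function(data, graph,
                                 estimand = c("direct", "total")) {
  estimand <- match.arg(estimand)
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!nrow(el)) return(empty_effect_table())
  el <- el[order(el$from, el$to), , drop = FALSE]
  out <- do.call(rbind, Map(function(s, t)
    estimate_effect(data, graph, s, t, estimand = estimand),
    el$from, el$to))
  rownames(out) <- NULL
  out
}
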