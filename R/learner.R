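## Constraint-based learner for the two-tier (genome instruments + traits)
## causal network. Skeleton: PC-stable with Fisher-z partial-correlation
## tests. Orientation: tier background knowledge (instrument edges point at
## traits), v-structures from separation sets, Meek rules 1-3, then a
## deterministic logged fallback for any residual undirected trait edges.

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\t")

#' Fisher-z partial correlation test
#'
#' Tests zero partial correlation of `x` and `y` given `S` from a
#' correlation matrix. With finite `n` the statistic
#' `sqrt(n - |S| - 3) * atanh(r)` is compared to a standard normal; with
#' `n = Inf` (oracle mode, analytic covariance) independence is declared
#' when the partial correlation is numerically zero.
#'
#' @param C correlation matrix with dimnames.
#' @param n sample size, or `Inf` for the population oracle.
#' @param x,y variable names.
#' @param S character vector of conditioning variable names (possibly empty).
#' @param tol numeric zero threshold used in oracle mode.
#' @return list with `pcor`, `p`.
#' @keywords internal
fisher_z_test <- function(C, n, x, y, S = character(0), tol = 1e-8) {
  idx <- c(x, y, S)
  sub <- C[idx, idx, drop = FALSE]
  P <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(P)) return(list(pcor = 1, p = 0))  # singular: treat as dependent
  pcor <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  pcor <- max(-1, min(1, pcor))
  if (!is.finite(n)) {
    return(list(pcor = pcor, p = if (abs(pcor) < tol) 1 else 0))
  }
  df <- n - length(S) - 3
  if (df < 1) return(list(pcor = pcor, p = NA_real_))
  z <- sqrt(df) * atanh(pcor * (1 - 1e-12))
  list(pcor = pcor, p = 2 * stats::pnorm(-abs(z)))
}

#' Estimate the skeleton of the two-tier network
#'
#' PC-stable search: starting from the complete graph over instruments and
#' traits (minus instrument-instrument pairs, excluded a priori — genome
#' components are orthogonal by construction and exogenous by design), an
#' edge is removed as soon as some conditioning set of adjacent nodes, of
#' size 0 up to `max_cond`, renders the pair independent at level `alpha`
#' by the Fisher-z partial-correlation test. Candidate conditioning sets at
#' each size are taken from the adjacency snapshot at the start of that
#' size, and nodes are scanned in sorted name order, making the result
#' independent of input column order.
#'
#' @param data samples x variables numeric matrix (instrument scores bound
#'   with traits), complete cases; or `NULL` when `cov_matrix` is given.
#' @param tiers named character vector (`"instrument"`/`"trait"`) covering
#'   every variable.
#' @param alpha significance level for the CI tests; default 0.001.
#' @param max_cond maximum conditioning-set size; `Inf` (default) grows sets until adjacency sizes are exhausted, the standard PC-algorithm schedule.
#' @param cov_matrix optional covariance/correlation matrix replacing
#'   `data` (oracle mode when `n = Inf`).
#' @param n sample size behind `cov_matrix`; `Inf` means population oracle.
#' @return object of class `gdag_skeleton`: list with `adjacency` (logical
#'   symmetric matrix), `sepsets` (list keyed by node pair), `tiers`,
#'   `alpha`, `n`, `n_tests`.
#' @export
estimate_skeleton <- function(data = NULL, tiers, alpha = 0.001, max_cond = Inf,
                              cov_matrix = NULL, n = NULL) {
  if (is.null(cov_matrix)) {
    stopifnot(is.matrix(data) || is.data.frame(data))
    data <- as.matrix(data)
    if (anyNA(data)) {
      data <- data[stats::complete.cases(data), , drop = FALSE]
    }
    n <- nrow(data)
    C <- stats::cor(data)
  } else {
    if (is.null(n)) n <- Inf
    C <- stats::cov2cor(cov_matrix)
  }
  nodes <- colnames(C)
  if (is.null(nodes)) stop("variables must be named")
  missing_tier <- setdiff(nodes, names(tiers))
  if (length(missing_tier))
    stop("no tier given for: ", paste(missing_tier, collapse = ", "))
  tiers <- tiers[nodes]
  stopifnot(alpha > 0, alpha <= 1, max_cond >= 0)

  adj <- matrix(TRUE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  inst <- nodes[tiers == "instrument"]
  adj[inst, inst] <- FALSE  # never tested, excluded a priori
  sepsets <- list()
  n_tests <- 0L
  skipped <- FALSE

  l <- 0L
  while (l <= max_cond) {
    if (is.finite(n) && n < l + 3) {
      warning("sample size ", n, " too small for conditioning sets of size ",
              l, "; larger sets skipped")
      skipped <- TRUE
      break
    }
    snapshot <- adj
    changed <- FALSE
    for (i in sort(nodes)) {
      for (j in sort(nodes[snapshot[i, ]])) {
        if (i >= j) next          # unordered pairs once; candidates from both ends
        if (!adj[i, j]) next
        removed <- FALSE
        for (anchor in c(i, j)) {
          other <- if (anchor == i) j else i
          cand <- sort(setdiff(nodes[snapshot[anchor, ]], other))
          if (length(cand) < l) next
          sets <- if (l == 0L) list(character(0)) else
            utils::combn(cand, l, simplify = FALSE)
          for (S in sets) {
            res <- fisher_z_test(C, n, i, j, S)
            n_tests <- n_tests + 1L
            if (!is.na(res$p) && res$p > alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepsets[[pair_key(i, j)]] <- S
              removed <- TRUE
              changed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
    # stop once no node retains enough neighbours to supply larger sets
    if (max(colSums(adj)) - 1L < l + 1L && !changed) break
    l <- l + 1L
  }
  structure(list(adjacency = adj, sepsets = sepsets, tiers = tiers,
                 alpha = alpha, n = n, n_tests = n_tests,
                 tests_skipped = skipped, C = C),
            class = "gdag_skeleton")
}

#' @export
print.gdag_skeleton <- function(x, ...) {
  cat("Skeleton over", ncol(x$adjacency), "nodes:",
      sum(x$adjacency) / 2, "edges (", x$n_tests, "CI tests, alpha =",
      x$alpha, ")\n")
  invisible(x)
}

#' Orient the skeleton into a causal graph
#'
#' Orientation proceeds in four deterministic stages: (1) background
#' knowledge — every instrument-trait edge points at the trait (genome
#' causes phenome, never the reverse); (2) unshielded colliders whose
#' middle node is absent from the separating set become v-structures;
#' (3) Meek rules 1-3 are applied to a fixed point; (4) any residual
#' undirected trait-trait edge is resolved by a logged fallback: it is
#' oriented away from the endpoint adjacent to more instruments (ties
#' broken lexicographically by node name), re-running the Meek closure
#' after each such orientation and reversing a fallback that would close a
#' directed cycle. An edge whose two directions are both forced by
#' conflicting rules is dropped and logged.
#'
#' @param skeleton a `gdag_skeleton` from [estimate_skeleton()].
#' @return a tiered causal graph (igraph) whose edges carry a `provenance`
#'   attribute (`"background"`, `"v-structure"`, `"meek"`, `"fallback"`),
#'   with attributes `conflicts` (data.frame of dropped edges) and
#'   `fallback_edges` (data.frame of fallback orientations).
#' @export
orient_edges <- function(skeleton) {
  stopifnot(inherits(skeleton, "gdag_skeleton"))
  adj <- skeleton$adjacency
  tiers <- skeleton$tiers
  nodes <- colnames(adj)
  # M[i, j] TRUE: edge between i and j, allowed direction i -> j.
  # Undirected edge: both M[i, j] and M[j, i]; directed: exactly one.
  M <- adj
  prov <- matrix(NA_character_, length(nodes), length(nodes),
                 dimnames = dimnames(M))
  conflicts <- data.frame(a = character(), b = character(),
                          stringsAsFactors = FALSE)

  has_dir_path <- function(from, to) {
    # BFS over currently directed edges only
    seen <- from
    frontier <- from
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier,
                                  function(v) nodes[M[v, ] & !M[, v]])))
      nxt <- setdiff(nxt, seen)
      if (to %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    FALSE
  }

  direct <- function(a, b, why) {
    # force a -> b; returns FALSE on conflict (edge then dropped)
    if (!M[a, b] && !M[b, a]) return(TRUE)        # edge already dropped
    if (M[a, b] && !M[b, a]) return(TRUE)         # already oriented a -> b
    drop_conflict <- function() {
      M[a, b] <<- FALSE
      M[b, a] <<- FALSE
      conflicts <<- rbind(conflicts, data.frame(a = a, b = b,
                                                stringsAsFactors = FALSE))
      FALSE
    }
    if (!M[a, b] && M[b, a]) return(drop_conflict())  # forced both ways
    # inconsistent sample CI results can ask an orientation that closes a
    # directed cycle; both directions are then implied, so the edge goes
    if (has_dir_path(b, a)) return(drop_conflict())
    M[b, a] <<- FALSE
    prov[a, b] <<- why
    TRUE
  }
  undirected <- function(a, b) M[a, b] && M[b, a]
  directed_into <- function(b) nodes[M[, b] & !M[b, ]]

  # (1) background knowledge: instrument edges point at traits
  for (i in nodes[tiers == "instrument"])
    for (j in nodes[M[i, ]]) direct(i, j, "background")

  # (2) classify every unshielded triple a - b - c (conservative-PC style).
  # The single recorded sepset is unreliable at finite n: conditioning on a
  # common child can nearly cancel an open confounding path, and a weak
  # instrument can look marginally independent of its target's children.
  # Instead the triple is probed with many candidate conditioning sets:
  #   collider       — a,c separable only WITHOUT b (the open two-edge path
  #                    a -> b <- c keeps them dependent under any set
  #                    containing b)
  #   non-collider   — a,c separable only WITH b (a chain or fork a - b - c
  #                    is blocked only by conditioning on b)
  #   ambiguous      — both achievable at level alpha: no orientation is
  #                    forced; the edge is left to later rules or fallback.
  # Under the population oracle every triple is determinate. Meek rule 1
  # below fires only on definite non-colliders, so a weak instrument
  # abstains instead of mis-orienting its target's parents.
  triple_status <- new.env(parent = emptyenv())
  classify_triple <- function(a, b, c, S0) {
    p_of <- function(S) fisher_z_test(skeleton$C, skeleton$n, a, c, S)$p
    cand <- list(character(0), S0, union(S0, b), setdiff(S0, b))
    for (anchor in c(a, c)) {
      other <- if (anchor == a) c else a
      nbs <- sort(setdiff(nodes[adj[anchor, ]], other))
      cand <- c(cand, as.list(nbs),
                if (length(nbs) >= 2L) utils::combn(nbs, 2L, simplify = FALSE))
    }
    cand <- unique(lapply(cand, sort))
    pv <- vapply(cand, p_of, 0)
    has_b <- vapply(cand, function(S) b %in% S, NA)
    sep_with <- any(pv[has_b] > skeleton$alpha, na.rm = TRUE)
    sep_without <- any(pv[!has_b] > skeleton$alpha, na.rm = TRUE)
    if (sep_without && !sep_with) "collider"
    else if (sep_with && !sep_without) "non-collider"
    else "ambiguous"
  }
  for (b in sort(nodes)) {
    if (tiers[b] == "instrument") next          # nothing points into these
    nb <- sort(nodes[adj[b, ]])
    if (length(nb) < 2L) next
    for (pair in utils::combn(nb, 2L, simplify = FALSE)) {
      a <- pair[1L]; c <- pair[2L]
      if (adj[a, c]) next                       # shielded
      S <- skeleton$sepsets[[pair_key(a, c)]]
      if (is.null(S)) next                      # untested pair (both instruments)
      status <- classify_triple(a, b, c, S)
      assign(paste(a, b, c, sep = "\t"), status, envir = triple_status)
      assign(paste(c, b, a, sep = "\t"), status, envir = triple_status)
      if (status != "collider") next
      if (undirected(a, b) || undirected(c, b) ||
          (M[a, b] && !M[b, a]) || (M[c, b] && !M[b, c])) {
        direct(a, b, "v-structure")
        direct(c, b, "v-structure")
      }
    }
  }
  noncollider <- function(a, b, c) {
    identical(get0(paste(a, b, c, sep = "\t"), envir = triple_status,
                   ifnotfound = "ambiguous"), "non-collider")
  }

  meek_closure <- function() {
    repeat {
      changed <- FALSE
      for (b in sort(nodes)) for (c in sort(nodes[M[b, ]])) {
        if (!undirected(b, c)) next
        # R1: a -> b, b - c, a and c nonadjacent, triple a-b-c a definite
        # non-collider  =>  b -> c (an undetected collider would otherwise
        # have been found at b)
        for (a in directed_into(b)) {
          if (a != c && !adj[a, c] && noncollider(a, b, c)) {
            if (direct(b, c, "meek")) changed <- TRUE
            break
          }
        }
        if (!undirected(b, c)) next
        # R2: b -> d -> c with b - c  =>  b -> c
        for (d in nodes[M[b, ] & !M[, b]]) {
          if (M[d, c] && !M[c, d]) {
            if (direct(b, c, "meek")) changed <- TRUE
            break
          }
        }
        if (!undirected(b, c)) next
        # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1/d2 nonadjacent => b -> c
        ds <- nodes[M[b, ] & M[, b]]
        ds <- ds[vapply(ds, function(d) M[d, c] && !M[c, d], NA)]
        if (length(ds) >= 2L) {
          for (pr in utils::combn(sort(ds), 2L, simplify = FALSE)) {
            if (!adj[pr[1L], pr[2L]]) {
              if (direct(b, c, "meek")) changed <- TRUE
              break
            }
          }
        }
      }
      if (!changed) break
    }
  }
  meek_closure()

  # (4) deterministic fallback for residual undirected trait-trait edges
  inst_count <- vapply(nodes, function(v)
    sum(adj[v, ] & tiers == "instrument"), 0L)
  fallback <- data.frame(source = character(), target = character(),
                         reversed = logical(), stringsAsFactors = FALSE)
  repeat {
    und <- which(M & t(M), arr.ind = TRUE)
    und <- und[und[, 1L] < und[, 2L], , drop = FALSE]
    if (!nrow(und)) break
    ends <- cbind(nodes[und[, 1L]], nodes[und[, 2L]])
    ord <- order(ends[, 1L], ends[, 2L])
    a <- ends[ord[1L], 1L]; b <- ends[ord[1L], 2L]
    # more-instrumented endpoint drives; lexicographic tie-break
    if (inst_count[b] > inst_count[a] ||
        (inst_count[b] == inst_count[a] && b < a)) {
      tmp <- a; a <- b; b <- tmp
    }
    rev <- FALSE
    if (has_dir_path(b, a)) { tmp <- a; a <- b; b <- tmp; rev <- TRUE }
    direct(a, b, "fallback")
    fallback <- rbind(fallback, data.frame(source = a, target = b,
                                           reversed = rev,
                                           stringsAsFactors = FALSE))
    meek_closure()
  }

  dir_idx <- which(M & !t(M), arr.ind = TRUE)
  edges <- data.frame(source = nodes[dir_idx[, 1L]],
                      target = nodes[dir_idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges$provenance <- prov[dir_idx]
  edges$provenance[is.na(edges$provenance)] <- "meek"
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  g <- causal_graph(edges, nodes = nodes, tiers = tiers)
  attr(g, "conflicts") <- conflicts
  attr(g, "fallback_edges") <- fallback
  if (nrow(conflicts))
    message(nrow(conflicts), " edge(s) dropped after orientation conflict")
  g
}
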