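# Exact permutation moments of the quadratic score statistic.
#
# Q = x' M x where x is a uniformly random permutation of the fixed residual
# vector r and M is the (weighted, rho-mixed) score kernel A R_rho A'.
# The first three moments of Q under permutation have closed forms in the
# power sums of r and contractions of M; a three-moment (shifted gamma) fit
# to them yields an analytic approximation to the permutation p-value that,
# unlike the asymptotic chi-square mixture, conditions on the observed
# phenotype vector. This is the same device behind moment-approximated
# Mantel and Moran randomization tests.
#
# E[Q^k] is assembled by enumerating set partitions of the 2k index slots:
# for each partition, the contraction of k copies of M constrained to
# distinct indices across blocks is obtained by Mobius inversion over
# coarser partitions of unconstrained contractions (each a small
# weighted-graph sum evaluated by vertex elimination), and the matching
# moment of the residual values is a distinct-tuple power-sum average.
# Everything is exact; the test suite checks against brute-force
# enumeration over all permutations at small n.

# all set partitions of 1..k as restricted-growth strings
set_partitions <- function(k) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(mx + 1L)) grow(c(prefix, b), max(mx, b))
  }
  grow(integer(0), 0L)
  out
}

# average over ordered distinct index tuples of prod r^powers, computed
# from power sums by the standard distinct-sum recursion
distinct_moment <- function(powers, S, n) {
  cache <- new.env(parent = emptyenv())
  N <- function(p) {
    p <- sort(p)
    key <- paste(p, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- if (length(p) == 1L) S[p] else {
      a <- p[length(p)]
      rest <- p[-length(p)]
      v <- S[a] * N(rest)
      for (t in seq_along(rest)) {
        bump <- rest
        bump[t] <- bump[t] + a
        v <- v - N(bump)
      }
      v
    }
    cache[[key]] <- val
    val
  }
  N(powers) / prod(n - seq_along(powers) + 1L)
}

# unconstrained contraction: vertices = blocks of the slot partition, each
# of the k M-factors an edge (within-block factor = a diag(M) loop);
# value = sum over all vertex labelings of the product of factor entries.
# Evaluated by eliminating a minimum-degree vertex at a time; with k <= 3
# every intermediate is a vector or matrix.
contract_free <- function(part, M, d, n, cache) {
  k <- length(part) %/% 2L
  edges <- lapply(seq_len(k), function(t) sort(part[c(2L * t - 1L, 2L * t)]))
  ord <- order(vapply(edges, paste, "", collapse = "-"))
  key <- paste(vapply(edges[ord], paste, "", collapse = "-"), collapse = "|")
  got <- cache[[key]]
  if (!is.null(got)) return(got)

  vec_fac <- list()                      # vertex -> accumulated n-vector
  mat_fac <- list()                      # list of (i, j, m): rows index i
  for (e in edges) {
    if (e[1L] == e[2L]) {
      v <- as.character(e[1L])
      vec_fac[[v]] <- if (is.null(vec_fac[[v]])) d else vec_fac[[v]] * d
    } else {
      mat_fac[[length(mat_fac) + 1L]] <- list(i = e[1L], j = e[2L], m = M)
    }
  }
  verts <- sort(unique(unlist(edges)))
  total <- 1
  while (length(verts) > 0L) {
    deg <- vapply(verts, function(v) {
      sum(vapply(mat_fac, function(f) v %in% c(f$i, f$j), logical(1)))
    }, integer(1))
    # merge parallel edges first so every degree-2 case is a clean join
    merged <- FALSE
    if (length(mat_fac) > 1L) {
      for (a in seq_len(length(mat_fac) - 1L)) {
        for (b in seq.int(a + 1L, length(mat_fac))) {
          if (mat_fac[[a]]$i == mat_fac[[b]]$i &&
              mat_fac[[a]]$j == mat_fac[[b]]$j) {
            mat_fac[[a]]$m <- mat_fac[[a]]$m * mat_fac[[b]]$m
            mat_fac[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (merged) next
    v <- verts[which.min(deg)]
    vn <- as.character(v)
    vv <- vec_fac[[vn]]
    touching <- which(vapply(mat_fac, function(f) v %in% c(f$i, f$j),
                             logical(1)))
    if (length(touching) == 0L) {
      total <- total * if (is.null(vv)) n else sum(vv)
    } else if (length(touching) == 1L) {
      f <- mat_fac[[touching]]
      mv <- if (f$i == v) f$m else t(f$m)     # rows index v
      other <- if (f$i == v) f$j else f$i
      w <- if (is.null(vv)) colSums(mv) else drop(crossprod(mv, vv))
      on <- as.character(other)
      vec_fac[[on]] <- if (is.null(vec_fac[[on]])) w else vec_fac[[on]] * w
      mat_fac[[touching]] <- NULL
    } else if (length(touching) == 2L) {
      f1 <- mat_fac[[touching[1L]]]
      f2 <- mat_fac[[touching[2L]]]
      m1 <- if (f1$i == v) f1$m else t(f1$m)  # rows index v
      m2 <- if (f2$i == v) f2$m else t(f2$m)
      o1 <- if (f1$i == v) f1$j else f1$i
      o2 <- if (f2$i == v) f2$j else f2$i
      if (!is.null(vv)) m1 <- m1 * vv         # column-recycling scales rows
      if (o1 == o2) {
        w <- colSums(m1 * m2)
        on <- as.character(o1)
        vec_fac[[on]] <- if (is.null(vec_fac[[on]])) w else vec_fac[[on]] * w
      } else {
        newm <- crossprod(m1, m2)             # (o1 x o2)
        lo <- min(o1, o2); hi <- max(o1, o2)
        mat_fac[[length(mat_fac) + 1L]] <-
          list(i = lo, j = hi, m = if (o1 <= o2) newm else t(newm))
      }
      mat_fac[touching] <- NULL
    } else {
      stop("unexpected contraction pattern")   # impossible for k <= 3
    }
    verts <- setdiff(verts, v)
  }
  cache[[key]] <- total
  total
}

# Mobius function of the partition lattice between a partition and one of
# its coarsenings (both as per-slot labels)
partition_mobius <- function(fine, coarse) {
  val <- 1
  for (cb in unique(coarse)) {
    nb <- length(unique(fine[coarse == cb]))
    val <- val * (-1)^(nb - 1L) * factorial(nb - 1L)
  }
  val
}

# all coarsenings of a partition, as per-slot labels
coarsenings <- function(part) {
  blocks <- sort(unique(part))
  lapply(set_partitions(length(blocks)), function(bp) bp[match(part, blocks)])
}

#' Exact permutation moments of a quadratic form
#'
#' Mean and second/third central moments of Q = x' M x where x is a
#' uniformly random permutation of the entries of `r`; exact for any
#' symmetric `M`.
#'
#' @param M symmetric matrix.
#' @param r numeric vector of values being permuted.
#' @return named vector `c(k1, k2, k3)`.
#' @export
quadform_perm_moments <- function(M, r) {
  n <- length(r)
  stopifnot(nrow(M) == n, ncol(M) == n)
  S <- vapply(1:6, function(k) sum(r^k), 0)
  d <- diag(M)
  cache <- new.env(parent = emptyenv())
  moment_k <- function(k) {
    total <- 0
    for (p in set_partitions(2L * k)) {
      Tp <- 0
      for (cp in coarsenings(p)) {
        Tp <- Tp + partition_mobius(p, cp) * contract_free(cp, M, d, n, cache)
      }
      if (Tp == 0) next
      total <- total + Tp * distinct_moment(as.integer(table(p)), S, n)
    }
    total
  }
  m1 <- moment_k(1L)
  m2 <- moment_k(2L)
  m3 <- moment_k(3L)
  c(k1 = m1, k2 = m2 - m1^2, k3 = m3 - 3 * m2 * m1 + 2 * m1^3)
}

#' Moment-approximated permutation p-value for a burden/kernel statistic
#'
#' Analytic approximation to [permutation_pvalue()]: the exact first three
#' permutation moments of Q_rho given the observed residual vector are
#' matched by a shifted gamma (three-moment chi-square) whose upper tail is
#' evaluated at the observed statistic. Conditions on the observed
#' phenotypes, which at a few hundred to a few thousand samples with very
#' rare variants tracks the permutation oracle considerably more closely
#' than the asymptotic chi-square mixture.
#'
#' The fit targets the informative (upper-tail) region. When the observed
#' statistic falls below the support start of the fitted gamma -- possible
#' deep in the left tail for strongly burden-weighted kernels, where any
#' p-value is close to 1 -- the p is reported as 1 with
#' `below_support = TRUE`; use [permutation_pvalue()] if that region
#' matters.
#'
#' @param G rare-variant genotype matrix (no missing entries).
#' @param w variant weight vector.
#' @param null [null_model()] output.
#' @param rho correlation parameter in [0, 1].
#' @return list with `p`, `Q`, `moments`, `below_support`.
#' @export
skat_perm_moment_pvalue <- function(G, w, null, rho = 0) {
  G <- as.matrix(G)
  stopifnot(ncol(G) == length(w))
  A <- sweep(G, 2, w, `*`)
  if (rho > 0) {
    m <- ncol(A)
    A <- A %*% rho_sqrt_mix(m, rho)
  }
  r <- null$residuals
  Q <- sum(drop(crossprod(A, r))^2)
  mom <- quadform_perm_moments(tcrossprod(A), r)
  if (mom["k3"] <= 0) {
    # fall back to a two-moment normal-deviate chi-square if skewness
    # degenerates (cannot occur for a positive semidefinite kernel with
    # non-degenerate residuals, but guarded anyway)
    z <- (Q - mom["k1"]) / sqrt(mom["k2"])
    return(list(p = unname(stats::pnorm(z, lower.tail = FALSE)), Q = Q,
                moments = mom, below_support = FALSE))
  }
  a <- mom["k3"] / (4 * mom["k2"])
  nu <- 8 * mom["k2"]^3 / mom["k3"]^2
  c0 <- mom["k1"] - a * nu
  below <- Q <= c0
  p <- if (below) 1 else
    stats::pchisq((Q - c0) / a, df = nu, lower.tail = FALSE)
  list(p = unname(p), Q = Q, moments = mom, below_support = below)
}
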