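#' Weighted directed interaction network
#'
#' Container for the interaction matrix \eqn{A = \{\alpha_{ij}\}} of a
#' multivariate Hawkes process (\eqn{\alpha_{ij}} is the influence of node
#' \eqn{j} on node \eqn{i}) together with the per-node base rates
#' \eqn{\rho_i}.  Networks generated by [make_network()] use the 0--1
#' connectivity convention: every present edge carries the identical weight
#' \eqn{R_0/(N c)}, where \eqn{c} is the fraction of ordered node pairs
#' (out of \eqn{N^2}) that are connected, so that the mean number of events
#' directly induced by one event is \eqn{R_0}.
#'
#' @param A square non-negative matrix of interaction weights.
#' @param rho per-node base rates; a scalar is recycled.
#' @param directed logical; `FALSE` asserts a symmetric matrix.
#' @param R0 the reproduction ratio the weights encode (kept so the network
#'   can be rescaled by [critical_R()]); inferred as `weight * N * c` for
#'   uniform-weight matrices when omitted.
#' @param model optional generator tag.
#' @param allow_diag permit non-zero diagonal entries (used by the uniform
#'   analytic benchmark and the block configurations).
#' @return An object of class `cascade_network` with fields `A`, `rho`,
#'   `N`, `c` (fraction of non-zero entries over \eqn{N^2}), `directed`,
#'   `R0` and `model`.
#' @export
cascade_network <- function(A, rho, directed = TRUE, R0 = NULL,
                            model = "custom", allow_diag = FALSE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("'A' must be square", call. = FALSE)
  if (any(A < 0)) stop("interaction weights must be non-negative", call. = FALSE)
  if (!allow_diag && any(diag(A) != 0))
    stop("self-loops are not allowed (set allow_diag = TRUE to permit them)",
         call. = FALSE)
  N <- nrow(A)
  rho <- rep_len(as.numeric(rho), N)
  if (any(rho < 0)) stop("base rates must be non-negative", call. = FALSE)
  if (!directed && !isTRUE(all.equal(A, t(A))))
    stop("undirected network requires a symmetric 'A'", call. = FALSE)
  cc <- sum(A > 0) / N^2
  if (is.null(R0)) {
    w <- unique(A[A > 0])
    R0 <- if (length(w) == 1L) w[1] * N * cc else NA_real_
  }
  structure(list(A = A, rho = rho, N = N, c = cc, directed = directed,
                 R0 = R0, model = model),
            class = "cascade_network")
}

#' @export
print.cascade_network <- function(x, ...) {
  cat(sprintf("Cascade network (%s): N = %d, %s, %d edges (c = %.4g)%s\n",
              x$model, x$N, if (x$directed) "directed" else "undirected",
              sum(x$A > 0), x$c,
              if (is.finite(x$R0)) sprintf(", R0 = %.4g", x$R0) else ""))
  invisible(x)
}

as_cascade_network <- function(x, rho = 1) {
  if (inherits(x, "cascade_network")) return(x)
  if (is.matrix(x)) return(cascade_network(x, rho, allow_diag = TRUE))
  stop("expected a cascade_network or a matrix", call. = FALSE)
}

# weighted adjacency from an igraph object (both directions for undirected)
adj_from_igraph <- function(g, weight) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  A * weight
}

#' Generate standard networks under the 0--1 connectivity convention
#'
#' Builds the network families used to map how structure shifts the SN
#' critical point: the fully connected uniform benchmark, Erdős--Rényi
#' random graphs, Barabási--Albert scale-free graphs, Watts--Strogatz
#' small-world graphs, regular ring lattices and Zachary's Karate Club.
#' Present edges carry weight \eqn{R_0/(N c)} with \eqn{c} the realized
#' fraction of connected ordered pairs, so the branching ratio per event is
#' \eqn{R_0} whenever in-degrees are uniform.
#'
#' Model specifics: `er` samples exactly `round(c * N^2)` ordered pairs
#' (halved and mirrored when undirected) without replacement; `ba` uses
#' linear preferential attachment with `m = c * N / 2` edges per new node;
#' `ws` rewires a ring of even degree `c * N` with probability `p_ws`
#' (default 0.1); `ring` is the `p_ws = 0` lattice; `uniform` is the
#' analytic all-to-all benchmark \eqn{\alpha_{ij} = R_0/N} *including* the
#' diagonal (set `diag = FALSE` to drop it); `karate` loads the bundled
#' 34-node friendship graph.
#'
#' @param model one of `"uniform"`, `"er"`, `"ba"`, `"ws"`, `"ring"`,
#'   `"karate"`.
#' @param N number of nodes (fixed at 34 for `karate`).
#' @param c target fraction of connected ordered pairs (ignored for
#'   `uniform` and `karate`).
#' @param R0 reproduction ratio encoded in the edge weight.
#' @param rho per-node base rate(s).
#' @param directed sample a directed graph (only `er` supports `TRUE`;
#'   the complex-network models follow the reciprocal-connection
#'   convention).
#' @param p_ws Watts--Strogatz rewiring probability.
#' @param diag keep the diagonal of the uniform benchmark.
#' @param seed optional RNG seed.
#' @return A [cascade_network()].
#' @examples
#' net <- make_network("er", N = 100, c = 0.1, R0 = 0.2, rho = 0.5, seed = 1)
#' net
#' make_network("karate", R0 = 0.25)
#' @export
make_network <- function(model = c("uniform", "er", "ba", "ws", "ring", "karate"),
                         N = NULL, c = NULL, R0, rho = 1,
                         directed = FALSE, p_ws = 0.1, diag = TRUE,
                         seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (model == "uniform") {
    if (is.null(N)) stop("'N' is required", call. = FALSE)
    A <- matrix(R0 / N, N, N)
    if (!diag) diag(A) <- 0
    return(cascade_network(A, rho, directed = FALSE, R0 = R0,
                           model = "uniform", allow_diag = diag))
  }
  if (model == "karate") {
    el <- utils::read.table(system.file("extdata", "karate_club.tsv",
                                        package = "cascadenet"),
                            comment.char = "#")
    N <- max(el)
    g <- igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
    cc <- 2 * nrow(el) / N^2
    A <- adj_from_igraph(g, R0 / (N * cc))
    return(cascade_network(A, rho, directed = FALSE, R0 = R0, model = "karate"))
  }
  if (is.null(N) || is.null(c)) stop("'N' and 'c' are required", call. = FALSE)
  if (model == "er") {
    E <- round(c * N^2)
    if (directed) {
      off <- which(diag(N) == 0)
      if (E > length(off)) stop("density 'c' unreachable without self-loops",
                                call. = FALSE)
      A <- matrix(0, N, N)
      A[sample(off, E)] <- 1
      g <- NULL
    } else {
      m <- round(E / 2)
      if (m > N * (N - 1) / 2) stop("density 'c' unreachable", call. = FALSE)
      g <- igraph::sample_gnm(N, m, directed = FALSE)
    }
  } else {
    k <- c * N
    if (model == "ba") {
      m <- max(1L, round(k / 2))
      g <- igraph::sample_pa(N, m = m, directed = FALSE)
    } else {                         # ws / ring
      nei <- round(k / 2)
      if (nei < 1) stop("density 'c' unreachable for a lattice", call. = FALSE)
      g <- igraph::sample_smallworld(1, N, nei = nei,
                                     p = if (model == "ws") p_ws else 0)
      g <- igraph::simplify(g)
    }
  }
  if (model == "er" && directed) {
    cc <- sum(A) / N^2
    A <- A * (R0 / (N * cc))
    return(cascade_network(A, rho, directed = TRUE, R0 = R0, model = "er"))
  }
  ccount <- 2 * igraph::ecount(g)
  cc <- ccount / N^2
  A <- adj_from_igraph(g, R0 / (N * cc))
  cascade_network(A, rho, directed = FALSE, R0 = R0, model = model)
}

#' Block "extreme" network configurations
#'
#' Analytically tractable block structures that bound the SN critical point:
#'
#' * kind `"i"` -- a fully connected group of `M` nodes (diagonal included,
#'   so \eqn{c = M^2/N^2}); the remaining nodes are isolated.
#' * kind `"ii"` -- the `M`-group of kind i additionally exchanges
#'   reciprocal connections with every remaining node
#'   (\eqn{c = (2MN - M^2)/N^2}).
#' * kind `"iii"` -- `M` nodes receive only directed connections from the
#'   other \eqn{N - M} nodes (\eqn{c = M(N-M)/N^2}); the adjacency is
#'   nilpotent, \eqn{A^2 = 0}, so \eqn{L = I + A} exactly.
#' * kind `"iv"` -- a strictly lower-triangular hierarchy: every node
#'   influences all nodes below it (\eqn{c = (N-1)/(2N)}).
#'
#' Kinds i and ii concentrate reciprocal connections and *lower* the
#' critical reproduction ratio (their \eqn{R_c(c)} curves cross near
#' \eqn{c = 0.2}); kinds iii and iv are purely feed-forward and *raise* it.
#'
#' @param kind `"i"`, `"ii"`, `"iii"` or `"iv"`.
#' @param N total number of nodes.
#' @param M group size (kinds i--iii), `1 <= M <= N`.
#' @param R0 reproduction ratio; edge weight is `R0 / (N * c)` with the
#'   kind's own `c`.
#' @param rho per-node base rate(s).
#' @return A [cascade_network()] (with diagonal entries for kinds i/ii).
#' @examples
#' make_extreme("iii", N = 12, M = 4, R0 = 0.3)
#' @export
make_extreme <- function(kind = c("i", "ii", "iii", "iv"), N, M = NULL, R0,
                         rho = 1) {
  kind <- match.arg(kind)
  if (kind != "iv") {
    if (is.null(M)) stop("'M' is required for kinds i-iii", call. = FALSE)
    if (M < 1 || M > N) stop("'M' out of range", call. = FALSE)
  }
  A <- matrix(0, N, N)
  cc <- switch(kind,
    i   = M^2 / N^2,
    ii  = (2 * M * N - M^2) / N^2,
    iii = M * (N - M) / N^2,
    iv  = (N - 1) / (2 * N))
  if (cc == 0) stop("configuration has no connections", call. = FALSE)
  w <- R0 / (N * cc)
  grp <- seq_len(if (kind == "iv") 0 else M)
  rest <- setdiff(seq_len(N), grp)
  if (kind == "i") {
    A[grp, grp] <- w
  } else if (kind == "ii") {
    A[grp, grp] <- w
    A[grp, rest] <- w
    A[rest, grp] <- w
  } else if (kind == "iii") {
    A[grp, rest] <- w            # group 1 receives from group 2
  } else {
    A[lower.tri(A)] <- w
  }
  cascade_network(A, rho, directed = kind %in% c("iii", "iv"), R0 = R0,
                  model = paste0("extreme_", kind),
                  allow_diag = kind %in% c("i", "ii"))
}

#' Average local clustering coefficient
#'
#' Watts--Strogatz local clustering of the binary undirected projection of
#' the network, averaged over nodes; nodes of degree < 2 contribute 0.
#'
#' @param net a [cascade_network()] (or adjacency matrix).
#' @return A value in \eqn{[0, 1]}.
#' @examples
#' tri <- cascade_network(0.1 * (matrix(1, 3, 3) - diag(3)), rho = 1)
#' clustering_coefficient(tri)    # 1
#' @export
clustering_coefficient <- function(net) {
  net <- as_cascade_network(net)
  B <- (net$A > 0) | (t(net$A) > 0)
  diag(B) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

# dense local-clustering tracker used inside the rewiring loop:
# Cl_i = (B^3)_ii / (k_i (k_i - 1)); equals igraph's localaverage/zero
clustering_dense <- function(A) {
  B <- ((A > 0) | (t(A) > 0)) * 1
  diag(B) <- 0
  k <- rowSums(B)
  tri <- diag(B %*% B %*% B)
  cl <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(cl)
}

#' Degree-based mean-field critical reproduction ratio
#'
#' Annealed (degree-class) approximation of the SN critical point for a
#' network specified only by its degree sequence: the interaction is
#' replaced by \eqn{\alpha_{ij} = R_0 k_i k_j / (N \langle k\rangle^2)}
#' (edge probability proportional to \eqn{k_i k_j}, weight
#' \eqn{R_0/(Nc)} with \eqn{c = \langle k\rangle/N}).  The rank-one
#' structure gives Leontief column sums \eqn{u_i = 1 + a k_i} with
#' \eqn{a = R_0 / (\langle k\rangle (1 - \theta))},
#' \eqn{\theta = R_0 \langle k^2\rangle / \langle k\rangle^2}, and the
#' cascading statistic reduces to
#' \eqn{C = \langle (1 + a k)^3 \rangle / \langle 1 + a k \rangle}.
#' `scale_free_Rc_meanfield` solves \eqn{C = 2} for \eqn{R_0}.  For
#' power-law degree distributions \eqn{P(k) \sim k^{-\gamma}} with
#' \eqn{\gamma \le 3}, \eqn{\langle k^2\rangle} grows with \eqn{N} and the
#' critical point vanishes as \eqn{N \to \infty}.  Degenerate (all-equal)
#' degree sequences recover the uniform-network value \eqn{1 - 1/\sqrt 2}.
#'
#' @param degrees positive degree sequence (one entry per node).
#' @return The approximate critical reproduction ratio.
#' @examples
#' scale_free_Rc_meanfield(rep(6, 100))     # 1 - 1/sqrt(2)
#' @export
scale_free_Rc_meanfield <- function(degrees) {
  degrees <- as.numeric(degrees)
  if (any(degrees <= 0)) stop("degrees must be positive", call. = FALSE)
  kbar <- mean(degrees); k2 <- mean(degrees^2)
  cmf <- function(R0) {
    theta <- R0 * k2 / kbar^2
    if (theta >= 1) return(Inf)
    u <- 1 + (R0 / (kbar * (1 - theta))) * degrees
    mean(u^3) / mean(u)
  }
  hi <- kbar^2 / k2 * (1 - 1e-9)
  f <- function(R0) cmf(R0) - 2
  if (f(hi * (1 - 1e-6)) < 0) return(NA_real_)   # cannot reach criticality
  uniroot(f, c(1e-10, hi * (1 - 1e-6)), tol = 1e-10)$root
}

#' Write / read a network as a plain-text edge list
#'
#' Format: `#` comment headers with `N`, `directed`, `R0` and the base
#' rates, followed by one `i j weight` line per directed edge (node indices
#' are 1-based).  Undirected networks store both directions.  Round-trips
#' at full double precision.
#'
#' @param net a [cascade_network()].
#' @param path file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a [cascade_network()].
#' @export
write_network <- function(net, path) {
  net <- as_cascade_network(net)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# cascade network: N=%d directed=%d R0=%s model=%s",
            net$N, as.integer(net$directed),
            format(net$R0, digits = 17), net$model),
    sprintf("# rho %s", paste(format(net$rho, digits = 17, trim = TRUE),
                              collapse = " ")),
    "# columns: i j weight (1-based node indices)"), con)
  idx <- which(net$A > 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(sprintf("%d %d %s", idx[, 1], idx[, 2],
                       format(net$A[idx], digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[0-9eEiInNfF.+-]+"), hdr))
    m <- unlist(m)
    if (length(m)) as.numeric(sub(paste0(key, "="), "", m[1])) else NULL
  }
  N <- get_num("N"); directed <- get_num("directed")
  if (is.null(N)) stop(sprintf("malformed network file '%s': missing N header",
                               path), call. = FALSE)
  R0 <- get_num("R0")
  model <- regmatches(hdr, regexpr("model=\\S+", hdr))
  model <- if (length(unlist(model))) sub("model=", "", unlist(model)[1]) else "custom"
  rho_line <- grep("^#\\s*rho\\b", lines, value = TRUE)
  rho <- if (length(rho_line))
    as.numeric(strsplit(trimws(sub("^#\\s*rho", "", rho_line[1])), "\\s+")[[1]])
  else 1
  body <- grep("^\\s*(#|$)", lines, invert = TRUE)
  A <- matrix(0, N, N)
  if (length(body)) {
    fields <- strsplit(trimws(lines[body]), "\\s+")
    bad <- which(lengths(fields) != 3L)
    if (length(bad))
      stop(sprintf("malformed network file '%s': expected 'i j weight' at line %d",
                   path, body[bad[1]]), call. = FALSE)
    i <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
    j <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(i) || anyNA(j) || anyNA(w))
      stop(sprintf("malformed network file '%s': non-numeric entry", path),
           call. = FALSE)
    A[cbind(i, j)] <- w
  }
  cascade_network(A, rho, directed = !isTRUE(directed == 0), R0 = R0,
                  model = model, allow_diag = TRUE)
}
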