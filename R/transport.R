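# Exact solver for the discrete transportation problem (Hitchcock form):
# minimise sum(plan * cost) subject to rowSums(plan) = supply,
# colSums(plan) = demand, plan >= 0. Transportation simplex: north-west
# corner start, MODI (u-v) optimality steps, Bland's rule as the
# anti-cycling fallback. Problem sizes here are histogram supports (tens to
# a few hundred bins), far below anything needing a specialised solver.

#' Solve a transportation problem exactly
#'
#' Minimises total transport cost between a supply and a demand vector over
#' a dense cost matrix; used as the LP engine behind the 2D earth mover's
#' distance and as the cross-check for the closed-form 1D construction. The
#' optimal cost is unique; where the optimal plan is degenerate the solver's
#' deterministic pivot order fixes which optimal plan is returned.
#'
#' @param supply,demand non-negative vectors with equal sums.
#' @param cost matrix of dimension \code{length(supply)} x
#'   \code{length(demand)}.
#' @return list with \code{plan} (matrix, marginals equal to the inputs)
#'   and \code{cost} (the minimum total cost).
#' @examples
#' res <- solveTransport(c(0.5, 0.5), c(0.25, 0.75),
#'                       matrix(c(0, 1, 1, 0), 2))
#' res$cost # 0.25
#' @export
solveTransport <- function(supply, demand, cost) {
  if (any(supply < 0) || any(demand < 0))
    stop("supply and demand must be non-negative")
  if (abs(sum(supply) - sum(demand)) > 1e-9 * max(sum(supply), 1))
    stop("supply and demand must balance")
  cost <- as.matrix(cost)
  if (nrow(cost) != length(supply) || ncol(cost) != length(demand))
    stop("cost matrix dimensions must match supply and demand lengths")

  keepI <- which(supply > 0)
  keepJ <- which(demand > 0)
  planFull <- matrix(0, length(supply), length(demand))
  if (!length(keepI) || !length(keepJ))
    return(list(plan = planFull, cost = 0))
  s <- supply[keepI]
  d <- demand[keepJ]
  d <- d * (sum(s) / sum(d)) # balance exactly despite rounding in the inputs
  cm <- cost[keepI, keepJ, drop = FALSE]
  m <- length(s)
  n <- length(d)

  # --- north-west corner initial basic feasible solution ----------------
  alloc <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  i <- 1L; j <- 1L
  sr <- s; dr <- d
  while (TRUE) {
    q <- min(sr[i], dr[j])
    alloc[i, j] <- q
    basis[i, j] <- TRUE
    sr[i] <- sr[i] - q
    dr[j] <- dr[j] - q
    if (i == m && j == n) break
    # move in one direction only, keeping exactly m + n - 1 basic cells
    if (i < m && (j == n || sr[i] <= dr[j])) i <- i + 1L else j <- j + 1L
  }

  tol <- 1e-12
  maxIter <- 200L * (m + n) + 5000L
  blandAfter <- 100L * (m + n) + 2500L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > maxIter)
      stop("transportation simplex failed to converge")
    # --- duals from the basis spanning tree ----------------------------
    u <- rep(NA_real_, m)
    v <- rep(NA_real_, n)
    u[1] <- 0
    queue <- c(1L)          # row nodes 1..m, col nodes m+1..m+n
    qpos <- 1L
    while (qpos <= length(queue)) {
      node <- queue[qpos]; qpos <- qpos + 1L
      if (node <= m) {
        js <- which(basis[node, ] & is.na(v))
        v[js] <- cm[node, js] - u[node]
        queue <- c(queue, m + js)
      } else {
        jj <- node - m
        is <- which(basis[, jj] & is.na(u))
        u[is] <- cm[is, jj] - v[jj]
        queue <- c(queue, is)
      }
    }
    # --- entering variable ---------------------------------------------
    red <- cm - outer(u, v, `+`)
    red[basis] <- 0
    if (iter <= blandAfter) {
      ent <- which.min(red)
      if (red[ent] >= -tol) break
    } else {
      neg <- which(red < -tol)
      if (!length(neg)) break
      ent <- neg[1]
    }
    ei <- ((ent - 1L) %% m) + 1L
    ej <- ((ent - 1L) %/% m) + 1L
    # --- cycle: unique path from row ei to col ej in the basis tree ----
    parent <- integer(m + n)
    seen <- logical(m + n)
    seen[ei] <- TRUE
    queue <- c(ei); qpos <- 1L
    target <- m + ej
    while (qpos <= length(queue)) {
      node <- queue[qpos]; qpos <- qpos + 1L
      if (node == target) break
      nbrs <- if (node <= m) m + which(basis[node, ]) else which(basis[, node - m])
      nbrs <- nbrs[!seen[nbrs]]
      seen[nbrs] <- TRUE
      parent[nbrs] <- node
      queue <- c(queue, nbrs)
    }
    path <- target
    while (path[1] != ei) path <- c(parent[path[1]], path)
    # consecutive node pairs are the basic cells of the cycle, in order
    nEdge <- length(path) - 1L
    ci <- integer(nEdge); cj <- integer(nEdge)
    for (k in seq_len(nEdge)) {
      a <- path[k]; b <- path[k + 1L]
      if (a <= m) { ci[k] <- a; cj[k] <- b - m } else { ci[k] <- b; cj[k] <- a - m }
    }
    minus <- seq(1L, nEdge, by = 2L)  # cycle signs: entering +, then -, +, ...
    allocMinus <- alloc[cbind(ci[minus], cj[minus])]
    lv <- which.min(allocMinus)
    theta <- allocMinus[lv]
    plus <- seq(2L, nEdge, by = 2L)
    alloc[cbind(ci[minus], cj[minus])] <- allocMinus - theta
    if (length(plus))
      alloc[cbind(ci[plus], cj[plus])] <- alloc[cbind(ci[plus], cj[plus])] + theta
    alloc[ei, ej] <- theta
    basis[ci[minus[lv]], cj[minus[lv]]] <- FALSE
    basis[ei, ej] <- TRUE
  }
  planFull[keepI, keepJ] <- alloc
  list(plan = planFull, cost = sum(planFull * cost))
}
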