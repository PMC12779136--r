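# Linear and mixed-integer programming layer.
#
# All constraint-based calculations (FBA, iMAT) reduce to LPs/MILPs over
# box-bounded variables with equality (steady state) and inequality
# constraints. The LP engine is a dense two-phase tableau simplex written
# for this package (Dantzig pricing with a Bland's-rule fallback against
# cycling); a best-bound branch-and-bound on top handles the binary
# variables of the iMAT program. Problem sizes here are desk scale
# (tens of reactions), where a dense tableau is simple and reliable.

# Two-phase tableau simplex for: min c'x, A x {<=,=} b, x >= 0.
# `sense`: character vector per row, "<=" or "=". Rows may have any sign
# of b; they are canonicalized internally. Returns list(status, x, objval).
lp_simplex <- function(cc, A, b, sense, tol = 1e-9, ftol = 1e-7) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(sense) == m, length(cc) == n)

  # canonicalize to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    sense[neg] <- ifelse(sense[neg] == "<=", ">=", sense[neg])
    # "=" stays "="; "<=" with b<0 became ">="
  }

  n_slack <- sum(sense == "<=") + sum(sense == ">=")
  n_art <- sum(sense == ">=") + sum(sense == "=")
  ncol_t <- n + n_slack + n_art
  T <- matrix(0, m, ncol_t)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  js <- n
  ja <- n + n_slack
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      js <- js + 1L
      T[i, js] <- 1
      basis[i] <- js
    } else if (sense[i] == ">=") {
      js <- js + 1L
      T[i, js] <- -1
      ja <- ja + 1L
      T[i, ja] <- 1
      basis[i] <- ja
      art_cols <- c(art_cols, ja)
    } else {
      ja <- ja + 1L
      T[i, ja] <- 1
      basis[i] <- ja
      art_cols <- c(art_cols, ja)
    }
  }
  rhs <- b

  run_phase <- function(obj, T, rhs, basis, allowed) {
    # reduced costs maintained by recomputation from basis (stable enough
    # at this scale); pivot loop on the tableau
    iter <- 0L
    max_iter <- 2000L + 200L * ncol(T)
    bland_after <- 500L + 20L * ncol(T)
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(NULL)
      cb <- obj[basis]
      # reduced costs: obj - cb' T
      red <- obj - drop(crossprod(cb, T))
      red[basis] <- 0
      cand <- which(red < -tol & allowed)
      if (length(cand) == 0L) {
        return(list(T = T, rhs = rhs, basis = basis))
      }
      q <- if (iter > bland_after) {
        cand[1L]  # Bland's rule
      } else {
        cand[which.min(red[cand])]
      }
      col <- T[, q]
      pos <- which(col > tol)
      if (length(pos) == 0L) return("unbounded")
      ratios <- rhs[pos] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      p <- ties[which.min(basis[ties])]  # Bland tie-break on leaving var
      piv <- T[p, q]
      T[p, ] <- T[p, ] / piv
      rhs[p] <- rhs[p] / piv
      other <- setdiff(seq_len(nrow(T)), p)
      f <- T[other, q]
      T[other, ] <- T[other, , drop = FALSE] - outer(f, T[p, ])
      rhs[other] <- rhs[other] - f * rhs[p]
      rhs[rhs < 0 & rhs > -ftol] <- 0
      basis[p] <- q
    }
  }

  if (n_art > 0) {
    obj1 <- numeric(ncol_t)
    obj1[art_cols] <- 1
    ph1 <- run_phase(obj1, T, rhs, basis, allowed = rep(TRUE, ncol_t))
    if (is.null(ph1) || identical(ph1, "unbounded")) {
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    }
    T <- ph1$T
    rhs <- ph1$rhs
    basis <- ph1$basis
    if (sum(rhs[basis %in% art_cols]) > ftol * max(1, max(abs(b)))) {
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    }
    # pivot out any artificial still basic at level ~0
    for (p in which(basis %in% art_cols)) {
      row <- T[p, seq_len(n + n_slack)]
      q <- which(abs(row) > tol)[1]
      if (is.na(q)) next  # redundant row; leave artificial basic at 0
      piv <- T[p, q]
      T[p, ] <- T[p, ] / piv
      rhs[p] <- rhs[p] / piv
      other <- setdiff(seq_len(m), p)
      f <- T[other, q]
      T[other, ] <- T[other, , drop = FALSE] - outer(f, T[p, ])
      rhs[other] <- rhs[other] - f * rhs[p]
      basis[p] <- q
    }
  }

  obj2 <- c(cc, numeric(n_slack + n_art))
  allowed <- c(rep(TRUE, n + n_slack), rep(FALSE, n_art))
  ph2 <- run_phase(obj2, T, rhs, basis, allowed)
  if (is.null(ph2)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  if (identical(ph2, "unbounded")) {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  x <- numeric(n)
  in_x <- ph2$basis <= n
  x[ph2$basis[in_x]] <- ph2$rhs[in_x]
  list(status = "optimal", x = x, objval = sum(cc * x))
}

#' Solve a box-bounded linear program
#'
#' Maximize (or minimize) `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and `lb <= x <= ub`. All bounds must be finite.
#'
#' @param obj Objective coefficient vector.
#' @param lb,ub Variable bounds (finite).
#' @param A_eq,b_eq Equality constraints (may be `NULL`).
#' @param A_le,b_le Inequality (`<=`) constraints (may be `NULL`).
#' @param maximize Logical; maximize when `TRUE` (default).
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), solution `x`, and `objval`.
#' @keywords internal
#' @export
solve_lp <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                     A_le = NULL, b_le = NULL, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub + 1e-12))
  shift <- lb
  rows <- list(diag(n))
  rhs <- list(ub - lb)
  sense <- rep("<=", n)
  if (!is.null(A_le) && nrow(A_le) > 0) {
    rows <- c(rows, list(A_le))
    rhs <- c(rhs, list(b_le - drop(A_le %*% shift)))
    sense <- c(sense, rep("<=", nrow(A_le)))
  }
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    rows <- c(rows, list(A_eq))
    rhs <- c(rhs, list(b_eq - drop(A_eq %*% shift)))
    sense <- c(sense, rep("=", nrow(A_eq)))
  }
  A <- do.call(rbind, rows)
  b <- unlist(rhs)
  cc <- if (maximize) -obj else obj
  res <- lp_simplex(cc, A, b, sense)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objval = NA_real_))
  }
  x <- res$x + shift
  list(status = "optimal", x = x, objval = sum(obj * x))
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Same problem form as [solve_lp()] with a subset of variables restricted
#' to {0, 1}. Uses best-bound-first branch and bound on the LP relaxation,
#' branching on the most fractional binary. When `integral_objective` is
#' `TRUE` (the iMAT case: the objective is a sum of binaries), node bounds
#' are floored, which prunes aggressively.
#'
#' @param obj,lb,ub,A_eq,b_eq,A_le,b_le,maximize As in [solve_lp()].
#' @param bin_idx Integer indices of the binary variables.
#' @param integral_objective Objective is integer-valued at feasible
#'   integer points.
#' @param gap Absolute optimality gap for termination (default 1e-6).
#' @param max_nodes Safety cap on explored nodes.
#' @return List with `status`, `x`, `objval`.
#' @keywords internal
#' @export
solve_milp <- function(obj, lb, ub, A_eq = NULL, b_eq = NULL,
                       A_le = NULL, b_le = NULL, bin_idx = integer(0),
                       maximize = TRUE, integral_objective = FALSE,
                       gap = 1e-6, max_nodes = 100000L) {
  if (length(bin_idx) == 0L) {
    return(solve_lp(obj, lb, ub, A_eq, b_eq, A_le, b_le, maximize))
  }
  sgn <- if (maximize) 1 else -1
  relax <- function(lbv, ubv) {
    solve_lp(sgn * obj, lbv, ubv, A_eq, b_eq, A_le, b_le, maximize = TRUE)
  }
  int_tol <- 1e-6
  best_x <- NULL
  best_val <- -Inf
  root <- relax(lb, ub)
  if (root$status != "optimal") {
    return(list(status = root$status, x = NULL, objval = NA_real_))
  }
  nodes <- list(list(lb = lb, ub = ub, bound = root$objval, sol = root$x))
  n_explored <- 0L
  while (length(nodes) > 0L && n_explored < max_nodes) {
    bounds <- vapply(nodes, `[[`, numeric(1), "bound")
    k <- which.max(bounds)
    node <- nodes[[k]]
    nodes[[k]] <- NULL
    nb <- if (integral_objective) floor(node$bound + 1e-7) else node$bound
    if (nb <= best_val + gap) next
    n_explored <- n_explored + 1L
    x <- node$sol
    yfrac <- abs(x[bin_idx] - round(x[bin_idx]))
    if (max(yfrac) <= int_tol) {
      if (node$bound > best_val) {
        best_val <- node$bound
        best_x <- x
      }
      next
    }
    j <- bin_idx[which.max(yfrac)]
    for (v in c(0, 1)) {
      lb2 <- node$lb
      ub2 <- node$ub
      lb2[j] <- v
      ub2[j] <- v
      child <- relax(lb2, ub2)
      if (child$status != "optimal") next
      cb <- if (integral_objective) floor(child$objval + 1e-7) else child$objval
      if (cb <= best_val + gap) next
      cy <- abs(child$x[bin_idx] - round(child$x[bin_idx]))
      if (max(cy) <= int_tol) {
        if (child$objval > best_val) {
          best_val <- child$objval
          best_x <- child$x
        }
      } else {
        nodes[[length(nodes) + 1L]] <- list(
          lb = lb2, ub = ub2, bound = child$objval, sol = child$x
        )
      }
    }
  }
  if (is.null(best_x)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  list(status = "optimal", x = best_x, objval = sgn * best_val)
}
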