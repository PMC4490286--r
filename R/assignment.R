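# Linear assignment (Hungarian algorithm with potentials) --------------------

#' Solve a linear assignment problem
#'
#' Finds the one-to-one assignment of rows to columns of a score matrix that
#' maximizes the total score (Hungarian algorithm, shortest-augmenting-path
#' form with dual potentials, O(n^2 m)). Rectangular matrices are handled by
#' assigning `min(nrow, ncol)` pairs; leftover rows are unassigned.
#'
#' @param score numeric matrix of pairwise scores (larger = better).
#' @return integer vector of length `nrow(score)`; element `i` is the column
#'   assigned to row `i`, or `NA` for unassigned rows.
#' @export
solve_assignment <- function(score) {
  if (!is.matrix(score) || !is.numeric(score) || anyNA(score))
    stop("`score` must be a numeric matrix without NA", call. = FALSE)
  nr0 <- nrow(score); nc0 <- ncol(score)
  transposed <- nr0 > nc0
  a <- if (transposed) t(-score) else -score   # minimize cost
  n <- nrow(a); m <- ncol(a)
  INF <- Inf
  # column index m+1 plays the role of the virtual column 0
  u <- numeric(n); v <- numeric(m + 1L)
  p <- integer(m + 1L)          # p[j] = row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      u0 <- if (i0 > 0L) u[i0] else 0
      free <- which(!used[seq_len(m)])
      cur <- a[i0, free] - u0 - v[free]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd]] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      v[usedj] <- v[usedj] - delta
      minv[seq_len(m)[!used[seq_len(m)]]] <-
        minv[seq_len(m)[!used[seq_len(m)]]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  col_of <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j] > 0L) col_of[p[j]] <- j
  if (transposed) {
    out <- rep(NA_integer_, nr0)
    for (i in seq_len(n)) if (!is.na(col_of[i])) out[col_of[i]] <- i
    out
  } else col_of
}
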