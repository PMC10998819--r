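# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so seeded package
#' functions do not disturb the user's random stream.
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-stream seed derived from a master seed and an index.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, index, stream = 0L) {
  base <- (as.double(seed) %% 2147483647) + 1
  mix <- (base * 48271 + as.double(index) * 7919 + as.double(stream) * 104729)
  as.integer(mix %% 2147483629)
}

# All permutations of 1..n as a matrix (n! rows). Used for exhaustive
# permutation tests; guarded to small n.
all_permutations <- function(n) {
  if (n > 8L) {
    stop("exhaustive enumeration limited to n <= 8 (", n, "! permutations requested)")
  }
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(rep.int(k, nrow(sub)),
                      matrix(rest[sub], nrow = nrow(sub)))
  }
  unname(do.call(rbind, out))
}

#' Compact letter display from a matrix of pairwise p-values
#'
#' Implements the insert-and-absorb algorithm: start from one letter
#' covering all levels; for every significant pair split each letter
#' containing both members, then absorb redundant subsets. Levels sharing
#' any letter are not significantly different at `alpha`.
#'
#' @param p_matrix symmetric matrix of pairwise p-values with level names
#'   on both dimensions; the diagonal is ignored.
#' @param alpha significance level for declaring a pair different.
#' @return named character vector of letter strings, one per level.
#' @export
compact_letters <- function(p_matrix, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  lev <- rownames(p_matrix)
  if (is.null(lev)) lev <- as.character(seq_len(nrow(p_matrix)))
  k <- length(lev)
  cols <- list(rep(TRUE, k))
  sig <- which(upper.tri(p_matrix) & !is.na(p_matrix) & p_matrix < alpha,
               arr.ind = TRUE)
  if (length(sig)) {
    for (row in seq_len(nrow(sig))) {
      i <- sig[row, 1L]
      j <- sig[row, 2L]
      for (ci in seq_along(cols)) {
        if (cols[[ci]][i] && cols[[ci]][j]) {
          split_a <- cols[[ci]]
          split_b <- cols[[ci]]
          split_a[j] <- FALSE
          split_b[i] <- FALSE
          cols[[ci]] <- split_a
          cols[[length(cols) + 1L]] <- split_b
        }
      }
      # absorb columns that are subsets of (or equal to) another column
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        if (drop[a]) next
        for (b in seq_along(cols)) {
          if (a == b || drop[b]) next
          if (all(cols[[a]] <= cols[[b]])) {
            if (all(cols[[a]] == cols[[b]])) {
              if (a > b) drop[a] <- TRUE
            } else {
              drop[a] <- TRUE
            }
            if (drop[a]) break
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  ord <- order(vapply(cols, function(x) which(x)[1L], integer(1)))
  cols <- cols[ord]
  if (length(cols) > length(letters)) {
    stop("more than 26 letter groups required; refusing to recycle letters")
  }
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  names(out) <- lev
  out
}

# Symmetric matrix coercion with id checks, shared by the permutation tests.
as_dist_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("`", arg, "` must be a 'dist' object or a square matrix")
  }
  if (max(abs(d - t(d))) > 1e-12) {
    stop("`", arg, "` is not symmetric")
  }
  d
}
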