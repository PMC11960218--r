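#' Sequential binary partitions and isometric log-ratio coordinates
#'
#' A 24-hour use-of-time composition (sleep, sedentary time, LPA, MVPA)
#' carries only relative information and is constrained to sum to 1440
#' minutes. Isometric log-ratio (ILR) coordinates map such a 4-part
#' composition to 3 unconstrained real coordinates that are orthonormal with
#' respect to the Aitchison geometry, so ordinary linear models apply.
#'
#' The basis is defined by a sequential binary partition (SBP): a sequence of
#' splits of the part set, each splitting one group produced earlier into a
#' numerator and a denominator group. For a split of \eqn{r} numerator parts
#' against \eqn{s} denominator parts the balance is
#' \deqn{z = \sqrt{rs/(r+s)} \, \ln(g(x_{num})/g(x_{den}))}
#' with \eqn{g} the geometric mean.
#'
#' The default partition isolates sleep from waking time, then sedentary time
#' from activity, then light from moderate-to-vigorous activity:
#' `{sleep | sed, lpa, mvpa}`, `{sed | lpa, mvpa}`, `{lpa | mvpa}`. Omnibus
#' interaction tests downstream are invariant to this choice; only individual
#' coefficients depend on it.
#'
#' @param sbp A signed contrast matrix with one row per balance and one
#'   column per part: `+1` numerator, `-1` denominator, `0` not involved.
#' @return `sbp_default()` returns the default contrast matrix;
#'   `sbp_basis()` returns the orthonormal basis matrix (balances in rows,
#'   parts in columns).
#' @examples
#' sbp_basis(sbp_default())
#' @export
sbp_default <- function() {
  m <- rbind(
    c( 1, -1, -1, -1),
    c( 0,  1, -1, -1),
    c( 0,  0,  1, -1)
  )
  dimnames(m) <- list(paste0("z", 1:3), BEHAVIOURS)
  m
}

#' @rdname sbp_default
#' @export
sbp_basis <- function(sbp = sbp_default()) {
  validate_sbp(sbp)
  if (is.null(rownames(sbp))) {
    rownames(sbp) <- paste0("z", seq_len(nrow(sbp)))
  }
  t(apply(sbp, 1, function(row) {
    r <- sum(row > 0)
    s <- sum(row < 0)
    out <- numeric(length(row))
    out[row > 0] <- sqrt(s / (r * (r + s)))
    out[row < 0] <- -sqrt(r / (s * (r + s)))
    out
  }))
}

# A valid SBP starts from the full part set and each row splits exactly one
# group formed so far. Also guards the +1/-1/0 coding.
validate_sbp <- function(sbp) {
  if (!is.matrix(sbp) || nrow(sbp) != ncol(sbp) - 1) {
    abort("`sbp` must be a (D-1) x D matrix")
  }
  if (!all(sbp %in% c(-1, 0, 1))) {
    abort("`sbp` entries must be -1, 0 or +1")
  }
  groups <- list(seq_len(ncol(sbp)))
  for (i in seq_len(nrow(sbp))) {
    involved <- which(sbp[i, ] != 0)
    hit <- which(vapply(groups, function(g) setequal(g, involved), logical(1)))
    if (length(hit) != 1) {
      abort(sprintf("`sbp` row %d does not split a group formed by earlier rows", i))
    }
    num <- which(sbp[i, ] > 0)
    den <- which(sbp[i, ] < 0)
    if (length(num) == 0 || length(den) == 0) {
      abort(sprintf("`sbp` row %d must have both numerator and denominator parts", i))
    }
    groups <- c(groups[-hit], list(num), list(den))
  }
  invisible(sbp)
}

#' Isometric log-ratio transform of use-of-time compositions
#'
#' Maps each row's 4-part composition to 3 ILR coordinates `z1, z2, z3`.
#' The transform is scale-invariant, so compositions may be supplied in
#' minutes (summing to 1440) or as proportions.
#'
#' @param data A data frame with columns `sleep`, `sed`, `lpa`, `mvpa`
#'   (strictly positive). Other columns are carried through.
#' @param sbp Sequential binary partition, as from [sbp_default()].
#' @param zero_replace Minutes substituted for zero parts before taking
#'   logs (multiplicative replacement: non-zero parts are scaled down to
#'   preserve the total). `NULL` (default) makes zero parts an error.
#' @return `data` with the four behaviour columns replaced by `z1..z3`.
#' @seealso [ilr_inverse()]
#' @export
ilr_transform <- function(data, sbp = sbp_default(), zero_replace = NULL) {
  x <- as.matrix(data[, BEHAVIOURS])
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("compositions must be finite and non-negative")
  }
  if (any(x == 0)) {
    if (is.null(zero_replace)) {
      abort(paste0(
        "zero parts found in ", sum(rowSums(x == 0) > 0), " composition(s); ",
        "supply `zero_replace` (e.g. 1 minute) to apply multiplicative replacement"
      ))
    }
    x <- t(apply(x, 1, function(row) {
      z <- row == 0
      if (!any(z)) return(row)
      tot <- sum(row)
      row[z] <- zero_replace
      row[!z] <- row[!z] * (tot - zero_replace * sum(z)) / tot
      row
    }))
  }
  V <- sbp_basis(sbp)
  z <- log(x) %*% t(V)
  colnames(z) <- rownames(V)
  out <- data[setdiff(names(data), BEHAVIOURS)]
  dplyr::bind_cols(as_tibble(out), as_tibble(z))
}

#' Inverse isometric log-ratio transform
#'
#' Back-transforms ILR coordinates to a positive composition closed to
#' `total` minutes.
#'
#' @param data A data frame with columns `z1`, `z2`, `z3`. Other columns are
#'   carried through.
#' @param sbp Sequential binary partition matching the forward transform.
#' @param total Closure total in minutes (1440 for a full day).
#' @return `data` with `z1..z3` replaced by `sleep`, `sed`, `lpa`, `mvpa`
#'   summing to `total`.
#' @export
ilr_inverse <- function(data, sbp = sbp_default(), total = 1440) {
  V <- sbp_basis(sbp)
  z <- as.matrix(data[, rownames(V)])
  clr <- z %*% V
  x <- exp(clr)
  x <- x / rowSums(x) * total
  colnames(x) <- BEHAVIOURS
  out <- data[setdiff(names(data), rownames(V))]
  dplyr::bind_cols(as_tibble(out), as_tibble(x))
}

#' Aitchison distance between two compositions
#'
#' Equals the Euclidean distance between the ILR images of the two
#' compositions (for any valid SBP).
#'
#' @param x,y Numeric vectors of 4 strictly positive parts, in the order
#'   sleep, sed, lpa, mvpa.
#' @return A non-negative scalar.
#' @export
aitchison_distance <- function(x, y) {
  clr <- function(v) log(v) - mean(log(v))
  sqrt(sum((clr(x) - clr(y))^2))
}
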