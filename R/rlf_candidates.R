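# Piecewise linear-in-rates RLF candidates and their evaluation.
#
# Two interchangeable shapes are supported:
#   * regional: V(r) = |c_k' r| on +-W_k, tied to a conic partition, and
#   * convex:   V(r) = max(0, max_k c_k' r) (the max form used by the
#     iterative algorithm and, after expansion, by Max-Min functions).

new_pwl_candidate <- function(C, partition = NULL, convex = FALSE,
                              method = "manual", xi = NULL, extra = list()) {
  C <- matrix(as.numeric(C), ncol = ncol(C))
  structure(c(list(C = C, partition = partition, convex = convex,
                   method = method, xi = xi), extra),
            class = "crn_pwl")
}

#' Create a piecewise linear-in-rates candidate
#'
#' @param C coefficient matrix, one row per linear piece (rates space).
#' @param partition a `crn_partition` when the candidate is defined
#'   region-wise (`V(r) = |c_k' r|` on the k-th region); `NULL` for the
#'   convex max form `V(r) = max(0, max_k c_k' r)`.
#' @param convex logical; `TRUE` for the max form.
#' @return a `crn_pwl` object.
#' @export
pwl_candidate <- function(C, partition = NULL, convex = is.null(partition)) {
  if (is.null(partition) && !convex) {
    stop("a regional candidate needs a partition")
  }
  if (!is.null(partition) && nrow(C) != nrow(partition$signatures)) {
    stop("need one row of C per kept region of the partition")
  }
  new_pwl_candidate(C, partition, convex)
}

#' Evaluate a rate-dependent Lyapunov function candidate
#'
#' Works for piecewise linear candidates (`crn_pwl`), Max-Min functions
#' (`crn_maxmin`) and piecewise quadratic candidates (`crn_pwq`).
#'
#' @param rlf the candidate.
#' @param r a rate vector, or a matrix with one rate vector per column.
#' @return numeric vector of values.
#' @export
evaluate_rlf <- function(rlf, r) {
  r <- as.matrix(r)
  UseMethod("evaluate_rlf")
}

#' @export
evaluate_rlf.crn_pwl <- function(rlf, r) {
  r <- as.matrix(r)
  z <- rlf$C %*% r
  if (rlf$convex) {
    pmax(apply(z, 2L, max), 0)
  } else {
    # regional form: |c_k' r| with k the region containing r.  For ties
    # (boundaries) continuity makes any containing region valid.
    part <- rlf$partition
    s <- part$H %*% r
    vapply(seq_len(ncol(r)), function(t) {
      sig <- sign(s[, t])
      for (k in seq_len(nrow(part$signatures))) {
        if (all(sig * part$signatures[k, ] >= 0) ||
            all(sig * part$signatures[k, ] <= 0)) {
          return(abs(z[k, t]))
        }
      }
      NA_real_
    }, numeric(1))
  }
}

#' @export
print.crn_pwl <- function(x, ...) {
  cat(sprintf("PWL rate-dependent Lyapunov candidate (%s form, %d pieces, method '%s')\n",
              if (x$convex) "convex max" else "regional", nrow(x$C), x$method))
  if (!is.null(x$xi)) cat("  species weights xi:", paste(x$xi, collapse = " "), "\n")
  invisible(x)
}

# rows of a convex max-form representation of a candidate; used by the
# verifier and the sampling oracles
convex_rows <- function(cand) {
  if (inherits(cand, "crn_maxmin")) return(maxmin_rows(cand))
  if (!inherits(cand, "crn_pwl")) stop("not a PWL candidate")
  if (cand$convex) return(cand$C)
  rbind(cand$C, -cand$C)
}

#' Serialize a certificate to structured text (JSON)
#'
#' Stores the coefficient matrix, partition data and method metadata so a
#' certificate can be archived and re-verified later.
#'
#' @param cand a `crn_pwl` or `crn_maxmin` certificate.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_certificate <- function(cand, file) {
  obj <- list(kind = class(cand)[1])
  if (inherits(cand, "crn_maxmin")) {
    obj$U <- cand$U
    obj$include_zero <- cand$include_zero
    obj$labels <- cand$labels
    obj$w <- cand$decomposition$w
  } else {
    obj$C <- cand$C
    obj$convex <- cand$convex
    obj$method <- cand$method
    if (!is.null(cand$xi)) obj$xi <- cand$xi
    if (!is.null(cand$partition)) {
      obj$H <- cand$partition$H
      obj$signatures <- cand$partition$signatures
    }
  }
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' Read back a serialized certificate
#'
#' @param file path written by [write_certificate()].
#' @return a `crn_pwl` or `crn_maxmin` object (partitions are restored
#'   structurally; re-verification is the caller's job).
#' @export
read_certificate <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (identical(obj$kind, "crn_maxmin")) {
    structure(list(U = as.matrix(obj$U), include_zero = obj$include_zero,
                   labels = obj$labels, decomposition = list(w = obj$w)),
              class = "crn_maxmin")
  } else {
    part <- NULL
    if (!is.null(obj$H)) {
      part <- structure(list(H = as.matrix(obj$H),
                             signatures = as.matrix(obj$signatures),
                             m = 2L * nrow(as.matrix(obj$signatures))),
                        class = "crn_partition")
    }
    new_pwl_candidate(as.matrix(obj$C), part, isTRUE(obj$convex),
                      method = obj$method %||% "archived",
                      xi = obj$xi)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
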