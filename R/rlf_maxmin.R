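# Graphical Max-Min construction.
#
# For M-networks (reversible reactions orientable so the irreversible
# subnetwork has a 1-dimensional flux kernel) satisfying two graphical side
# conditions, V(r) = max(R) - min(R) is an RLF, where R collects the
# weighted net rates (R_j - R_-j)/w_j of oriented reversible reactions and
# R_j/w_j of irreversible ones. For orientations whose irreversible
# subnetwork has only the zero flux ({0} kernel, e.g. a pure binding
# network), the constant 0 is appended to R with all weights 1, which
# reproduces |R_1 - R_-1| for the simple binding reaction.

#' Graphical Max-Min RLF construction
#'
#' Checks, per acceptable orientation of the reversible reactions, that (i)
#' every species is a reactant of exactly one reaction of the oriented
#' irreversible subnetwork (at most one in the zero-flux case) and (ii) no
#' product of an oriented-forward reversible reaction is a product of
#' another reaction of the subnetwork. Non-autocatalytic networks only.
#'
#' @param net a `crn_network`.
#' @return a `crn_maxmin` object on success, otherwise a list with
#'   `status = "conditions_not_met"` and the failed condition.
#' @export
graphical_maxmin <- function(net) {
  if (net$autocatalytic) {
    return(list(status = "conditions_not_met",
                condition = "network is autocatalytic"))
  }
  decomps <- m_decomposition(net, all_orientations = TRUE)
  if (!length(decomps)) {
    return(list(status = "conditions_not_met",
                condition = "not an M-network (no orientation with dim ker <= 1)"))
  }
  # prefer positive-flux (dim 1) orientations, in search order
  ord <- order(vapply(decomps, function(d) d$zero_flux, logical(1)))
  decomps <- decomps[ord]
  last_fail <- NULL
  for (md in decomps) {
    chk <- maxmin_conditions(net, md)
    if (chk$ok) return(maxmin_from_decomposition(net, md))
    last_fail <- chk$condition
  }
  list(status = "conditions_not_met", condition = last_fail)
}

maxmin_conditions <- function(net, md) {
  cols <- md$columns
  Asub <- net$A[, cols, drop = FALSE]
  Bsub <- net$B[, cols, drop = FALSE]
  cnt <- rowSums(Asub > 0)
  if (md$zero_flux) {
    if (any(cnt > 1)) {
      sp <- net$species[which(cnt > 1)[1]]
      return(list(ok = FALSE, condition = sprintf(
        "species %s is a reactant of more than one oriented reaction", sp)))
    }
  } else if (any(cnt != 1)) {
    sp <- net$species[which(cnt != 1)[1]]
    return(list(ok = FALSE, condition = sprintf(
      "species %s is a reactant of %d oriented reactions (needs exactly 1)",
      sp, cnt[which(cnt != 1)[1]])))
  }
  rev_members <- unlist(net$reversible_pairs)
  for (t in seq_along(cols)) {
    j <- cols[t]
    if (!(j %in% rev_members)) next          # condition (ii): reversible only
    prods <- which(Bsub[, t] > 0)
    if (!length(prods)) next
    others <- Bsub[prods, -t, drop = FALSE]
    if (any(others > 0)) {
      bad <- prods[which(rowSums(others > 0) > 0)[1]]
      return(list(ok = FALSE, condition = sprintf(
        "product %s of oriented reversible reaction %s is produced elsewhere",
        net$species[bad], net$labels[j])))
    }
  }
  list(ok = TRUE)
}

maxmin_from_decomposition <- function(net, md) {
  nu <- n_reactions(net)
  partner <- integer(nu)
  for (p in net$reversible_pairs) {
    partner[p[1]] <- p[2]; partner[p[2]] <- p[1]
  }
  U <- NULL; labels <- character(0)
  for (t in seq_along(md$columns)) {
    j <- md$columns[t]
    u <- numeric(nu)
    u[j] <- 1
    lab <- net$labels[j]
    if (partner[j] > 0) {
      u[partner[j]] <- -1
      lab <- paste0(net$labels[j], "-", net$labels[partner[j]])
    }
    u <- u / md$w[t]
    if (md$w[t] != 1) lab <- sprintf("(%s)/%g", lab, md$w[t])
    U <- rbind(U, u)
    labels <- c(labels, lab)
  }
  rownames(U) <- NULL
  structure(list(U = U, labels = labels, include_zero = md$zero_flux,
                 decomposition = md, status = "ok"),
            class = "crn_maxmin")
}

# convex max-form rows of V(r) = max(R) - min(R): all pairwise differences
maxmin_rows <- function(mm) {
  U <- mm$U
  if (isTRUE(mm$include_zero)) U <- rbind(U, 0)
  q <- nrow(U)
  rows <- list()
  for (a in seq_len(q)) for (b in seq_len(q)) {
    if (a != b) rows[[length(rows) + 1L]] <- U[a, ] - U[b, ]
  }
  do.call(rbind, rows)
}

#' @export
evaluate_rlf.crn_maxmin <- function(rlf, r) {
  r <- as.matrix(r)
  z <- rlf$U %*% r
  if (isTRUE(rlf$include_zero)) z <- rbind(z, 0)
  apply(z, 2L, max) - apply(z, 2L, min)
}

#' @export
print.crn_maxmin <- function(x, ...) {
  cat("Max-Min RLF: V = max(R) - min(R) with R = {",
      paste(x$labels, collapse = ", "),
      if (isTRUE(x$include_zero)) ", 0" else "", "}\n", sep = "")
  invisible(x)
}
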