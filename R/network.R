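#' Chemical reaction networks
#'
#' A `crn_network` holds the stoichiometry of a chemical reaction network:
#' the ordered species list, the reactant coefficient matrix `A` (alpha_ij),
#' the product coefficient matrix `B` (beta_ij), the stoichiometry matrix
#' `Gamma = B - A` (all species x reactions), and the pairing of reversible
#' reactions. A reversible reaction is stored as two adjacent columns, the
#' forward column immediately followed by its reverse.
#'
#' @name crn_network
NULL

.species_re <- "^[A-Za-z][A-Za-z0-9_+*']*$"

new_network <- function(A, B, species, reversible_pairs = list(),
                        labels = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  n <- nrow(A); nu <- ncol(A)
  stopifnot(nrow(B) == n, ncol(B) == nu, length(species) == n)
  if (anyDuplicated(species)) stop("species names must be unique")
  if (any(A < 0) || any(B < 0) || any(A != round(A)) || any(B != round(B))) {
    stop("stoichiometry coefficients must be nonnegative integers")
  }
  empty <- colSums(A) == 0 & colSums(B) == 0
  if (any(empty)) stop("reaction with empty reactant and product complex")
  if (is.null(labels)) labels <- paste0("R", seq_len(nu))
  for (p in reversible_pairs) {
    j <- p[1]; jr <- p[2]
    if (!all(A[, jr] == B[, j]) || !all(B[, jr] == A[, j])) {
      stop("reverse column is not the mirror of its forward column")
    }
  }
  Gamma <- B - A
  rownames(A) <- rownames(B) <- rownames(Gamma) <- species
  colnames(A) <- colnames(B) <- colnames(Gamma) <- labels
  structure(list(
    species = species,
    A = A, B = B, Gamma = Gamma,
    reversible_pairs = reversible_pairs,
    labels = labels,
    autocatalytic = any(A > 0 & B > 0)
  ), class = "crn_network")
}

n_species <- function(net) length(net$species)
n_reactions <- function(net) ncol(net$Gamma)

# indices of columns that are the reverse member of a reversible pair
reverse_columns <- function(net) {
  vapply(net$reversible_pairs, `[`, numeric(1), 2L)
}

parse_complex <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") {
    if (txt == "") stop(sprintf("line %d: empty complex (use 0)", line_no))
    return(list())
  }
  # '+' is a complex separator only when surrounded by whitespace, so that
  # species names may themselves end in '+' (phosphorylated forms)
  if (grepl("^\\+(\\s|$)", txt) || grepl("\\s\\+\\s*$", txt)) {
    stop(sprintf("line %d: dangling '+' in complex '%s'", line_no, txt))
  }
  terms <- strsplit(txt, "\\s+\\+\\s+")[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*\\*?\\s*(.*)$", tm))[[1]]
    coef <- if (m[2] == "") 1L else as.integer(m[2])
    sp <- trimws(m[3])
    if (!grepl(.species_re, sp)) {
      stop(sprintf("line %d: malformed species term '%s'", line_no, tm))
    }
    if (is.na(coef) || coef < 1) {
      stop(sprintf("line %d: invalid stoichiometric coefficient in '%s'",
                   line_no, tm))
    }
    out[[sp]] <- (if (is.null(out[[sp]])) 0L else out[[sp]]) + coef
  }
  out
}

#' Parse a reaction-list text into a network
#'
#' One reaction per line, `<complex> -> <complex>` or `<complex> <-> <complex>`,
#' where a complex is `0` (empty; inflow/outflow) or terms like
#' `2 E + X` joined by ` + `. Species names match
#' `[A-Za-z][A-Za-z0-9_+*']*`, so primed and phosphorylated names such as
#' `S+` or `X'` are single species. Lines starting with `#` are comments.
#' A `<->` line produces two adjacent columns (forward then reverse)
#' registered in `reversible_pairs`.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines.
#' @param species optional character vector fixing the species order;
#'   defaults to order of first appearance.
#' @return a `crn_network`.
#' @examples
#' net <- parse_network("
#'   S + E <-> SE
#'   SE -> S+ + E
#'   S+ + F <-> S+F
#'   S+F -> S + F")
#' net
#' @export
parse_network <- function(text, species = NULL) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(text)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no reactions found")
  if (anyDuplicated(lines)) {
    warning("duplicate reaction lines: ",
            paste(unique(lines[duplicated(lines)]), collapse = "; "))
  }
  rxns <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]; no <- lines_no[k]
    rev_split <- regexpr("<->", ln, fixed = TRUE)
    if (rev_split > 0) {
      sides <- strsplit(ln, "<->", fixed = TRUE)[[1]]
      rev <- TRUE
    } else if (grepl("->", ln, fixed = TRUE)) {
      sides <- strsplit(ln, "->", fixed = TRUE)[[1]]
      rev <- FALSE
    } else {
      stop(sprintf("line %d: no reaction arrow ('->' or '<->') found", no))
    }
    if (length(sides) != 2L) {
      stop(sprintf("line %d: expected exactly one arrow", no))
    }
    lhs <- parse_complex(sides[1], no)
    rhs <- parse_complex(sides[2], no)
    if (!length(lhs) && !length(rhs)) {
      stop(sprintf("line %d: both complexes empty", no))
    }
    rxns[[length(rxns) + 1L]] <- list(lhs = lhs, rhs = rhs, rev = rev)
  }
  build_network(rxns, species = species)
}

# rxns: list of list(lhs = named count list/vector, rhs = ..., rev = logical)
build_network <- function(rxns, species = NULL) {
  seen <- character(0)
  for (r in rxns) seen <- union(seen, c(names(r$lhs), names(r$rhs)))
  if (is.null(species)) species <- seen else {
    if (!all(seen %in% species)) {
      stop("species order does not cover: ",
           paste(setdiff(seen, species), collapse = ", "))
    }
  }
  n <- length(species)
  cols_A <- list(); cols_B <- list(); labels <- character(0)
  pairs <- list()
  side_vec <- function(side) {
    v <- numeric(n); names(v) <- species
    for (sp in names(side)) v[sp] <- side[[sp]]
    unname(v)
  }
  for (k in seq_along(rxns)) {
    r <- rxns[[k]]
    a <- side_vec(r$lhs); b <- side_vec(r$rhs)
    cols_A[[length(cols_A) + 1L]] <- a
    cols_B[[length(cols_B) + 1L]] <- b
    labels <- c(labels, paste0("R", k))
    if (isTRUE(r$rev)) {
      cols_A[[length(cols_A) + 1L]] <- b
      cols_B[[length(cols_B) + 1L]] <- a
      labels <- c(labels, paste0("R-", k))
      j <- length(cols_A)
      pairs[[length(pairs) + 1L]] <- c(j - 1L, j)
    }
  }
  new_network(do.call(cbind, cols_A), do.call(cbind, cols_B),
              species, pairs, labels)
}

#' Build a network from stoichiometric matrices
#'
#' @param A,B nonnegative integer reactant and product coefficient matrices
#'   (species x reactions).
#' @param species species names; defaults to rownames of `A` or `X1..Xn`.
#' @param reversible_pairs list of 2-vectors `c(j_forward, j_reverse)`.
#' @return a `crn_network`.
#' @export
network_from_matrices <- function(A, B, species = rownames(A),
                                  reversible_pairs = list()) {
  if (is.null(species)) species <- paste0("X", seq_len(nrow(A)))
  new_network(A, B, species, reversible_pairs)
}

format_complex <- function(coef, species) {
  nz <- which(coef > 0)
  if (!length(nz)) return("0")
  paste(ifelse(coef[nz] > 1, paste(coef[nz], species[nz]), species[nz]),
        collapse = " + ")
}

#' @export
format.crn_network <- function(x, ...) {
  out <- character(0)
  skip <- logical(n_reactions(x))
  rev_of <- integer(n_reactions(x))
  for (p in x$reversible_pairs) rev_of[p[1]] <- p[2]
  for (j in seq_len(n_reactions(x))) {
    if (skip[j]) next
    arrow <- if (rev_of[j] > 0) "<->" else "->"
    if (rev_of[j] > 0) skip[rev_of[j]] <- TRUE
    out <- c(out, sprintf("%s: %s %s %s", x$labels[j],
                          format_complex(x$A[, j], x$species), arrow,
                          format_complex(x$B[, j], x$species)))
  }
  out
}

#' @export
print.crn_network <- function(x, ...) {
  cat(sprintf("Chemical reaction network: %d species, %d reaction columns (%d reversible pairs)\n",
              n_species(x), n_reactions(x), length(x$reversible_pairs)))
  cat(paste0("  ", format(x), collapse = "\n"), "\n")
  if (x$autocatalytic) cat("  [autocatalytic]\n")
  invisible(x)
}

#' Export the stoichiometric matrices as delimited text
#'
#' Writes `A`, `B` and `Gamma` as tab-separated tables with species row names
#' and reaction column labels.
#'
#' @param net a `crn_network`.
#' @param file path of the output file.
#' @return invisibly, the path.
#' @export
write_network_matrices <- function(net, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in c("A", "B", "Gamma")) {
    cat(sprintf("# %s\n", nm), file = con)
    utils::write.table(net[[nm]], con, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(file)
}
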