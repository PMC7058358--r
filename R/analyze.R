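# End-to-end analysis: structural screens, necessary conditions, and the
# ladder of construction methods.

#' Analyze a network for structural attractivity
#'
#' Runs, in order: structural summary (conservation, deficiency, flux),
#' necessary-condition screens (minimal siphons, P0 property, robust
#' non-degeneracy), then the construction ladder (graphical Max-Min,
#' sum-of-currents, LP over the default partition, iterative algorithm and,
#' optionally, the piecewise quadratic SDP). Stops at the first verified
#' certificate unless `all_methods = TRUE`; every certificate is re-verified
#' by the LP verifier before being reported.
#'
#' The verdict is one of
#' * `"attractive"` — a verified RLF was constructed;
#' * `"excluded"` — a necessary condition for a PWL RLF fails
#'   (P0 violation, or critical siphon under the preclusion clauses);
#' * `"inconclusive"` — neither.
#'
#' @param net a `crn_network`.
#' @param methods construction methods to try, in order.
#' @param all_methods run every method even after a success.
#' @param include_sdp append the SDP relaxation to the ladder.
#' @param partition_cap skip partition-based methods when `H = Gamma` has
#'   more rows than this.
#' @return an object of class `crn_report`.
#' @export
analyze_network <- function(net,
                            methods = c("maxmin", "soc", "lp", "iterate"),
                            all_methods = FALSE, include_sdp = FALSE,
                            partition_cap = 14L) {
  if (include_sdp) methods <- unique(c(methods, "sdp"))
  cons <- conservation_analysis(net)
  defic <- deficiency(net)
  as1 <- !is.null(cons$positive_flux)
  siph <- tryCatch(siphon_analysis(net), error = function(e)
    structure(list(minimal_siphons = list(), complete = FALSE,
                   note = conditionMessage(e)), class = "crn_siphons"))
  p0 <- check_p0(net)
  nondeg <- check_robust_nondegeneracy(net)

  excluded <- FALSE; exclusion <- character(0)
  if (identical(p0$verdict, "fail")) {
    excluded <- TRUE
    exclusion <- c(exclusion, sprintf(
      "P0 condition fails (minor on {%s})",
      paste(p0$witness$species, collapse = ", ")))
  }
  if (isTRUE(siph$preclusion$applies)) {
    excluded <- TRUE
    exclusion <- c(exclusion, paste("critical siphon preclusion:",
                                    paste(siph$preclusion$clauses,
                                          collapse = "; ")))
  }

  part <- NULL
  need_part <- any(c("soc", "lp", "sdp") %in% methods) &&
    nrow(net$Gamma) <= partition_cap
  results <- list()
  certificate <- NULL
  if (!excluded || all_methods) {
    for (m in methods) {
      res <- tryCatch({
        switch(m,
          maxmin = graphical_maxmin(net),
          soc = {
            if (is.null(part) && need_part) part <- build_partition(net)
            if (is.null(part)) list(status = "skipped",
                                    reason = "partition too large")
            else construct_soc(net, part)
          },
          lp = {
            if (is.null(part) && need_part) part <- build_partition(net)
            if (is.null(part)) list(status = "skipped",
                                    reason = "partition too large")
            else construct_pwl_lp(net, part)
          },
          iterate = iterate_convex(net),
          sdp = {
            if (is.null(part) && need_part) part <- build_partition(net)
            if (is.null(part)) list(status = "skipped",
                                    reason = "partition too large")
            else construct_pwq_sdp(net, part)
          })
      }, error = function(e) list(status = "error",
                                  reason = conditionMessage(e)))
      ok <- !is.null(res$status) && res$status == "ok"
      verified <- FALSE
      if (ok && m != "sdp") {
        verified <- isTRUE(verify_pwl(net, res)$pass)
      } else if (ok && m == "sdp") {
        verified <- isTRUE(sampled_kernel_check(net, res)$pass) &&
          isTRUE(sampled_decrease_check(net, res,
                                        n_samples = 2000L)$max_violation <= 1e-6)
      }
      results[[m]] <- list(result = res, verified = verified)
      if (verified && is.null(certificate)) {
        certificate <- res
        if (!all_methods) break
      }
    }
  }

  verdict <- if (!is.null(certificate)) "attractive"
  else if (excluded) "excluded" else "inconclusive"
  structure(list(
    network = net,
    structure = list(n_species = n_species(net),
                     n_reactions = n_reactions(net),
                     conservative = cons$is_conservative,
                     n_laws = ncol(cons$left_kernel),
                     as1 = as1, deficiency = defic$deficiency),
    screens = list(p0 = p0, siphons = siph, nondegeneracy = nondeg),
    constructions = results,
    certificate = certificate,
    exclusion = exclusion,
    verdict = verdict
  ), class = "crn_report")
}

#' @export
print.crn_report <- function(x, ...) {
  cat("== Network analysis report ==\n")
  st <- x$structure
  cat(sprintf("species %d | reactions %d | conservative %s | laws %d | positive flux (AS1) %s | deficiency %d\n",
              st$n_species, st$n_reactions, st$conservative, st$n_laws,
              st$as1, st$deficiency))
  cat("P0 screen:", x$screens$p0$verdict, "\n")
  if (isTRUE(x$screens$siphons$complete)) {
    cat(sprintf("Minimal siphons: %d (%d critical)\n",
                length(x$screens$siphons$minimal_siphons),
                length(x$screens$siphons$critical)))
  }
  cat("Robustly non-degenerate (rho = 1):",
      x$screens$nondegeneracy$nondegenerate, "\n")
  for (m in names(x$constructions)) {
    r <- x$constructions[[m]]
    status <- r$result$status %||%
      (if (inherits(r$result, "list")) "failed" else "ok")
    cat(sprintf("  method %-8s: %s%s\n", m, status,
                if (r$verified) " [verified]" else ""))
  }
  cat("VERDICT:", toupper(x$verdict), "\n")
  if (length(x$exclusion)) cat("  ", paste(x$exclusion, collapse = "\n   "), "\n")
  invisible(x)
}

#' CLI exit code for a report
#'
#' `0` attractive, `1` PWL-RLF excluded, `2` inconclusive.
#' @param report a `crn_report`.
#' @return integer exit code.
#' @export
report_exit_code <- function(report) {
  switch(report$verdict, attractive = 0L, excluded = 1L, inconclusive = 2L, 3L)
}
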