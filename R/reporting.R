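## Per-system summaries and comparative arithmetic: integer percent
## changes between systems, per-chain energy normalization, and the
## NP^a-nPEG_b-X nomenclature parser.

#' Percent change between two system values
#'
#' \code{100 * (other - reference) / reference}, rounded half away from
#' zero to an integer. Decreases are reported as a positive magnitude with
#' \code{direction = "decrease"}. With \code{use_magnitude = TRUE} the
#' comparison is done on absolute values (the convention for interaction
#' energies, which are discussed by magnitude).
#'
#' @param reference reference value (nonzero)
#' @param other comparison value
#' @param use_magnitude compare absolute values
#' @return list with integer \code{percent} (>= 0), \code{direction}
#'   (\code{"increase"}, \code{"decrease"} or \code{"none"}) and the
#'   unrounded \code{raw} signed percentage
#' @export
percent_change <- function(reference, other, use_magnitude = FALSE) {
  if (use_magnitude) { reference <- abs(reference); other <- abs(other) }
  if (reference == 0) stop("percent change undefined for zero reference")
  raw <- 100 * (other - reference) / reference
  pct <- as.integer(round_half_away(abs(raw)))
  structure(list(percent = pct,
                 direction = if (pct == 0) "none"
                             else if (raw > 0) "increase" else "decrease",
                 raw = raw),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, ...) {
  cat(sprintf("%d%% %s (raw %+.2f%%)\n", x$percent, x$direction, x$raw))
  invisible(x)
}

#' Normalize a group energy by the number of chains
#'
#' @param energy total energy in kcal/mol
#' @param n_chains number of grafted chains (> 0)
#' @return kcal/mol per chain
#' @export
per_chain_normalize <- function(energy, n_chains) {
  if (n_chains <= 0) stop("n_chains must be > 0")
  energy / n_chains
}

#' Parse a coated-nanosystem name
#'
#' Grammar \code{NP^a-nPEG_b-X}: core material (e.g. \code{ND},
#' \code{TiO2}), core diameter \code{a} in nm, chain count \code{n},
#' PEG molecular weight \code{b} in Da, and solution-side terminal group
#' \code{X} (\code{OH} or \code{CH3}). An optional \code{2} prefix and
#' \code{^far}/\code{^close} suffix mark the two-particle setups.
#'
#' @param name system name, e.g. \code{"ND^2-50PEG_500-OH"}
#' @return list with \code{core}, \code{diameter_nm}, \code{n_chains},
#'   \code{peg_mw}, \code{terminal}, \code{n_particles}, \code{variant}
#' @export
parse_system_name <- function(name) {
  pat <- paste0("^(2)?([A-Za-z][A-Za-z0-9]*)\\^([0-9]+)-",
                "([0-9]+)PEG_([0-9]+)-(OH|CH3)(\\^(far|close))?$")
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (!length(m))
    stop("malformed system name '", name,
         "'; expected NP^a-nPEG_b-X (e.g. ND^2-50PEG_500-OH, ",
         "optionally 2...^far/^close for two-particle setups)")
  list(core = m[3], diameter_nm = as.numeric(m[4]),
       n_chains = as.integer(m[5]), peg_mw = as.numeric(m[6]),
       terminal = m[7],
       n_particles = if (nzchar(m[2])) 2L else 1L,
       variant = if (nzchar(m[9])) m[9] else NA_character_)
}

#' Published per-system structural and energetic means
#'
#' Loads the transcription of the per-system summary tables shipped with
#' the package (mean and standard deviation per quantity and system):
#' chain radius of gyration \code{Rg}, end-to-end distance \code{h},
#' terminus-core distance \code{d}, layer thickness \code{thk} (Angstrom),
#' and the group-pair nonbonded energies \code{E_NP_PEG},
#' \code{E_PEG_PEG}, \code{E_NP_water}, \code{E_PEG_water} (kcal/mol).
#' Test and comparison input only; these numbers are never produced by the
#' package's analyses.
#'
#' @return data.frame with columns \code{system}, \code{quantity},
#'   \code{mean}, \code{sd}
#' @export
published_tables <- function() {
  path <- system.file("extdata", "published_tables.csv",
                      package = "nanobrush", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Compare systems quantity by quantity
#'
#' Computes rounded integer percent changes between pairs of systems for
#' named quantities, from a long table of per-system means (such as
#' \code{\link{published_tables}} or rows assembled from
#' \code{\link{chain_metrics}} / \code{\link{energy_series}} output).
#'
#' @param summaries data.frame with columns \code{system},
#'   \code{quantity}, \code{mean}
#' @param plan data.frame with columns \code{quantity},
#'   \code{reference}, \code{other}, and optional logicals
#'   \code{use_magnitude} and \code{per_chain} (divide by the chain count
#'   parsed from each system name before comparing)
#' @return data.frame of comparisons: quantity, reference, other,
#'   percent, direction; rows whose quantities are missing are skipped
#'   with a warning
#' @export
compare_systems <- function(summaries, plan) {
  if (is.null(plan$use_magnitude)) plan$use_magnitude <- FALSE
  if (is.null(plan$per_chain)) plan$per_chain <- FALSE
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    pick <- function(sys) {
      v <- summaries$mean[summaries$system == sys &
                          summaries$quantity == plan$quantity[i]]
      if (!length(v)) return(NA_real_)
      v[1]
    }
    ref <- pick(plan$reference[i]); oth <- pick(plan$other[i])
    if (is.na(ref) || is.na(oth)) {
      warning("quantity '", plan$quantity[i], "' missing for pair ",
              plan$reference[i], " / ", plan$other[i], "; row skipped")
      next
    }
    if (isTRUE(plan$per_chain[i])) {
      ref <- per_chain_normalize(ref,
               parse_system_name(plan$reference[i])$n_chains)
      oth <- per_chain_normalize(oth,
               parse_system_name(plan$other[i])$n_chains)
    }
    pc <- percent_change(ref, oth,
                         use_magnitude = isTRUE(plan$use_magnitude[i]))
    rows[[length(rows) + 1]] <- data.frame(
      quantity = plan$quantity[i], reference = plan$reference[i],
      other = plan$other[i], percent = pc$percent,
      direction = pc$direction, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Canonical comparison plan for the shipped system tables
#'
#' The standard battery of pairwise comparisons across the seven coated
#' systems: grafting density (25 vs 50 vs 100 chains on the 2 nm core),
#' core dimension (2 vs 5 nm at equal grafting density, with the
#' water-polymer energy normalized per chain), polymer length (500 vs
#' 1000 Da), and core material (diamond vs titania). Energy rows compare
#' magnitudes.
#'
#' @return plan data.frame for \code{\link{compare_systems}}
#' @export
standard_comparison_plan <- function() {
  p <- function(quantity, reference, other, use_magnitude = FALSE,
                per_chain = FALSE)
    data.frame(quantity = quantity, reference = reference, other = other,
               use_magnitude = use_magnitude, per_chain = per_chain,
               stringsAsFactors = FALSE)
  rbind(
    ## grafting density: 100 vs 50 chains, then 100 vs 25
    p(c("Rg", "h", "d", "thk"), "ND^2-50PEG_500-OH", "ND^2-100PEG_500-OH"),
    p(c("Rg", "h", "d", "thk"), "ND^2-25PEG_500-OH", "ND^2-100PEG_500-OH"),
    ## core dimension at 4.6 chains/nm^2
    p(c("Rg", "h", "thk"), "ND^2-100PEG_500-OH", "ND^5-360PEG_500-OH"),
    p("E_PEG_water", "ND^2-100PEG_500-OH", "ND^5-360PEG_500-OH",
      use_magnitude = TRUE, per_chain = TRUE),
    ## polymer length: 500 vs 1000 Da on the 5 nm core
    p(c("Rg", "h", "d", "thk"), "ND^5-360PEG_500-OH",
      "ND^5-360PEG_1000-OH"),
    p(c("E_PEG_PEG", "E_PEG_water"), "ND^5-360PEG_500-OH",
      "ND^5-360PEG_1000-OH", use_magnitude = TRUE),
    ## core material: diamond vs titania
    p(c("Rg", "h", "d", "thk"), "ND^2-50PEG_500-CH3",
      "TiO2^2-50PEG_500-CH3")
  )
}

#' Render a comparison table
#'
#' @param comparisons output of \code{\link{compare_systems}}
#' @param format \code{"markdown"} or \code{"csv"}
#' @return character vector of rendered lines
#' @export
render_comparisons <- function(comparisons,
                               format = c("markdown", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(comparisons, con, row.names = FALSE)
    close(con)
    return(out)
  }
  c("| quantity | reference | other | change |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %d%% %s |", comparisons$quantity,
            comparisons$reference, comparisons$other,
            comparisons$percent, comparisons$direction))
}
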