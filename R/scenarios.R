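#' One phase of a case-control study design
#'
#' @param panel character vector of panel names, one per arm
#' @param n_cases,n_controls integer case/control counts per arm
#' @return data.frame with columns `panel`, `n_cases`, `n_controls`
#' @export
phase_design <- function(panel, n_cases, n_controls) {
  if (length(panel) < 1) stop("a phase needs at least one arm")
  d <- data.frame(panel = as.character(panel),
                  n_cases = as.integer(n_cases),
                  n_controls = as.integer(n_controls),
                  stringsAsFactors = FALSE)
  if (any(d$n_cases < 0 | d$n_controls < 0)) {
    stop("case and control counts must be non-negative")
  }
  d
}

#' Two-phase study scenario
#'
#' A scenario is a named pair of phases; evidence from every (phase, panel)
#' arm is combined by summing NCPs, so a phase with zero samples leaves the
#' scenario equal to the other phase alone.
#'
#' @param name scenario label
#' @param phase1,phase2 [phase_design()] data.frames; `phase2` may be `NULL`
#' @return object of class `scenario`
#' @export
scenario <- function(name, phase1, phase2 = NULL) {
  if (is.null(phase2)) {
    phase2 <- phase_design(phase1$panel[1], 0L, 0L)
  }
  structure(list(name = name, phase1 = phase1, phase2 = phase2),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (total n = %d)\n", x$name, scenario_total(x)))
  for (ph in c("phase1", "phase2")) {
    arms <- x[[ph]]
    cat(" ", ph, ":",
        paste(sprintf("%s %d/%d", arms$panel, arms$n_cases, arms$n_controls),
              collapse = " + "), "\n")
  }
  invisible(x)
}

#' Total sample size (cases + controls, both phases)
#' @param x a [scenario()]
#' @return integer total
#' @export
scenario_total <- function(x) {
  arms <- rbind(x$phase1, x$phase2)
  sum(arms$n_cases) + sum(arms$n_controls)
}

#' Divide cases and controls evenly across panels
#'
#' Integer division with any remainder assigned one extra unit to the
#' earliest panels in list order, so totals are conserved exactly.
#'
#' @param n_cases,n_controls totals to distribute
#' @param panels character vector of panel names
#' @return a [phase_design()]
#' @export
split_equal <- function(n_cases, n_controls, panels) {
  if (length(panels) < 1) stop("panel list must be non-empty")
  k <- length(panels)
  split1 <- function(n) {
    base <- n %/% k
    base + as.integer(seq_len(k) <= n %% k)
  }
  phase_design(panels, split1(n_cases), split1(n_controls))
}

#' Build a scenario from a declarative configuration
#'
#' The configuration is a list (typically parsed from YAML or JSON) with
#' elements `name`, `phase1` and `phase2`. Each phase has `panels` (or
#' singular `panel`), `cases`, `controls` and an optional
#' `split: equal | explicit`. With `split = "equal"` (the default when one
#' total is given for several panels) the totals are distributed by
#' [split_equal()]; with `split = "explicit"`, `cases`/`controls` are
#' vectors aligned with `panels`.
#'
#' @param config named list as above
#' @return a [scenario()]
#' @export
build_scenario <- function(config) {
  if (is.null(config$phase1)) stop("config must define phase1")
  parse_phase <- function(ph) {
    panels <- ph$panels %||% ph$panel
    if (is.null(panels)) stop("phase config needs 'panel' or 'panels'")
    panels <- as.character(unlist(panels))
    split <- ph$split %||%
      if (length(ph$cases) == length(panels)) "explicit" else "equal"
    if (split == "explicit") {
      if (length(ph$cases) != length(panels) ||
          length(ph$controls) != length(panels)) {
        stop("explicit split needs one cases/controls entry per panel")
      }
      phase_design(panels, unlist(ph$cases), unlist(ph$controls))
    } else {
      split_equal(sum(unlist(ph$cases)), sum(unlist(ph$controls)), panels)
    }
  }
  p1 <- parse_phase(config$phase1)
  p2 <- if (is.null(config$phase2)) NULL else parse_phase(config$phase2)
  scenario(config$name %||% "scenario", p1, p2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario configuration file (YAML or JSON)
#' @param path configuration file; `.json` is parsed with jsonlite,
#'   anything else with yaml
#' @return a [scenario()]
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_scenario(cfg)
}

#' The three standard two-phase design presets
#'
#' Total sample sizes of 10,000 (2,500/2,500 per phase), 20,000
#' (5,000/5,000 per phase) and 80,000 (10,000/10,000 phase 1 and
#' 30,000/30,000 phase 2). Phase 1 is always drawn from the reference
#' European panel; phase 2 totals are split equally across the requested
#' panels.
#'
#' @param total one of 10000, 20000, 80000
#' @param phase2_panels character vector of phase-2 panels
#' @param phase1_panel phase-1 panel (default `"CEU"`)
#' @return a [scenario()]
#' @export
scenario_preset <- function(total, phase2_panels = "CEU",
                            phase1_panel = "CEU") {
  sizes <- list(
    `10000` = c(2500L, 2500L),
    `20000` = c(5000L, 5000L),
    `80000` = c(10000L, 30000L))
  key <- as.character(total)
  if (!key %in% names(sizes)) {
    stop("total must be one of 10000, 20000, 80000")
  }
  sz <- sizes[[key]]
  scenario(
    name = sprintf("%s, phase2=%s", key, paste(phase2_panels, collapse = "+")),
    phase1 = phase_design(phase1_panel, sz[1], sz[1]),
    phase2 = split_equal(sz[2], sz[2], phase2_panels))
}
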