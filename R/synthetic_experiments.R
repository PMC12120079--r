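# Record-level synthetic experiments: two-color mixing (the oracle for
# gating and doublet-rate estimation) and editing-efficiency screen plates
# (the oracle for plate summaries).

#' Specification of a two-color mixing experiment
#'
#' Emulates mixing two cell lines carrying spectrally distinct fluorescent
#' proteins in proportion `p : (1 - p)`, imaging them, and gating against a
#' non-fluorescent control. Each cell is a doublet with probability
#' `doublet_rate`; a doublet's channel means are the sums of two independent
#' parents (each parent drawn from population A with probability `p`, so a
#' doublet is heterotypic with probability `2 p (1 - p)`).
#'
#' Intensity model: a cell positive for a channel draws its mean from
#' `lnorm(pos_meanlog, pos_sdlog)`; all other channel values are cellular
#' autofluorescence, `lnorm(neg_meanlog, neg_sdlog)`. The autofluorescence
#' distribution is deliberately broad on the log scale (default sdlog 0.8) so
#' that its 99.9th percentile sits far above twice its median — then a
#' homotypic doublet's summed background stays below the gate and the
#' double-positive fraction is dominated by heterotypic doublets, the
#' assumption behind the doubling argument in [doublet_rate()].
#'
#' @param n_cells Number of mixed cells (events).
#' @param mix_fraction Design proportion `p` of population A, in (0, 1).
#' @param doublet_rate Fraction of events that are doublets, in `[0, 1)`.
#' @param channels Length-2 channel names; population A is positive in the
#'   first, population B in the second.
#' @param pos_meanlog,pos_sdlog Log-normal parameters of the positive signal.
#' @param neg_meanlog,neg_sdlog Log-normal parameters of autofluorescence.
#' @param control_n Size of the non-fluorescent gating-control population.
#' @param seed Integer seed.
#' @return A list of class `mix_spec`.
#' @export
mix_spec <- function(n_cells = 20000, mix_fraction = 0.5, doublet_rate = 0.018,
                     channels = c("mNG", "mApple"),
                     pos_meanlog = log(500), pos_sdlog = 0.5,
                     neg_meanlog = log(10), neg_sdlog = 0.8,
                     control_n = 10000, seed = 1) {
  if (mix_fraction <= 0 || mix_fraction >= 1)
    stop_value("`mix_fraction` must lie strictly between 0 and 1")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop_value("`doublet_rate` must lie in [0, 1)")
  if (length(channels) != 2) stop_value("`channels` must name exactly 2 channels")
  structure(list(n_cells = n_cells, mix_fraction = mix_fraction,
                 doublet_rate = doublet_rate, channels = channels,
                 pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
                 control_n = control_n, seed = seed),
            class = "mix_spec")
}

#' Generate a two-color mixing experiment with truth labels
#'
#' @param spec A [mix_spec()].
#' @return A list of class `mixing_experiment`: `records` (tibble with
#'   `cell_id`, `condition = "mix"`, `mean_<channel>` columns, and truth
#'   columns `population` ("A"/"B" for singlets, "AA"/"AB"/"BB" for
#'   doublets), `is_doublet`, `heterotypic`), `controls` (tibble of
#'   non-fluorescent control records, `condition = "WT"`), and `spec`.
#' @export
make_mixing_experiment <- function(spec) {
  stopifnot(inherits(spec, "mix_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    p <- spec$mix_fraction
    is_doublet <- runif(n) < spec$doublet_rate
    parent1 <- ifelse(runif(n) < p, "A", "B")
    parent2 <- ifelse(runif(n) < p, "A", "B")   # used only for doublets
    draw <- function(pop_vec) {
      # channel value for one parent of populations in pop_vec
      pos <- rlnorm(n, spec$pos_meanlog, spec$pos_sdlog)
      neg <- rlnorm(n, spec$neg_meanlog, spec$neg_sdlog)
      list(A = ifelse(pop_vec == "A", pos, neg),
           B = ifelse(pop_vec == "B", pos, neg))
    }
    d1 <- draw(parent1)
    d2 <- draw(parent2)
    chA <- ifelse(is_doublet, d1$A + d2$A, d1$A)
    chB <- ifelse(is_doublet, d1$B + d2$B, d1$B)
    population <- ifelse(is_doublet,
                         paste0(pmin(parent1, parent2), pmax(parent1, parent2)),
                         parent1)
    records <- tibble(cell_id = seq_len(n), condition = "mix")
    records[[paste0("mean_", spec$channels[1])]] <- chA
    records[[paste0("mean_", spec$channels[2])]] <- chB
    records$population <- population
    records$is_doublet <- is_doublet
    records$heterotypic <- is_doublet & parent1 != parent2
    controls <- tibble(cell_id = seq_len(spec$control_n), condition = "WT")
    controls[[paste0("mean_", spec$channels[1])]] <-
      rlnorm(spec$control_n, spec$neg_meanlog, spec$neg_sdlog)
    controls[[paste0("mean_", spec$channels[2])]] <-
      rlnorm(spec$control_n, spec$neg_meanlog, spec$neg_sdlog)
    structure(list(records = records, controls = controls, spec = spec),
              class = "mixing_experiment")
  })
}

#' Summarize a gated two-color mix
#'
#' Gates the mixed records, reports the single- and double-positive
#' fractions (over all gated cells) and the doublet-rate estimate implied by
#' the double-positive fraction and the design mix proportion.
#'
#' @param records Tibble of mixed-cell records with `mean_<channel>` columns.
#' @param gates A `cyto_gates` object covering both channels.
#' @param channels Length-2 channel names (A first).
#' @param mix_fraction Design mix proportion `p` of population A.
#' @return One-row tibble: `n_cells`, `frac_pos_a`, `frac_pos_b`,
#'   `frac_double`, `mix_fraction_a`, `doublet_rate`.
#' @export
mixing_summary <- function(records, gates, channels, mix_fraction = 0.5) {
  gated <- apply_gates(records, gates)
  pa <- gated[[paste0("positive_", channels[1])]]
  pb <- gated[[paste0("positive_", channels[2])]]
  frac_double <- mean(pa & pb)
  tibble(n_cells = nrow(gated),
         frac_pos_a = mean(pa), frac_pos_b = mean(pb),
         frac_double = frac_double,
         mix_fraction_a = mix_fraction,
         doublet_rate = doublet_rate(min(frac_double,
                                         2 * mix_fraction * (1 - mix_fraction)),
                                     mix_fraction))
}

# screen plates ---------------------------------------------------------------

#' Specification of a synthetic editing-efficiency screen plate
#'
#' Emulates a two-factor plate screen (prime-editor plasmid dose x MLH1dn
#' dose, 8 x 11 = 88 conditions by default): each well's cell count is
#' Poisson around `control_n` times a proliferation surface — MLH1dn
#' suppresses proliferation dose-dependently — and its positive count is
#' binomial with an efficiency surface that peaks at a low editor dose and an
#' intermediate MLH1dn dose. A no-plasmid control well provides both the
#' non-fluorescent gating population and the survival denominator.
#'
#' @param pe_ng Prime-editor plasmid doses (ng/well).
#' @param mlh1_ng MLH1dn plasmid doses (ng/well).
#' @param efficiency Function `(pe, mlh1) -> fraction in [0, 1]`: the true
#'   editing efficiency surface.
#' @param proliferation Function `(pe, mlh1) -> rate >= 0`: expected cell
#'   count relative to the no-plasmid control.
#' @param control_n Expected cells in the control well.
#' @param pos_meanlog,pos_sdlog,neg_meanlog,neg_sdlog Intensity log-normal
#'   parameters, as in [mix_spec()].
#' @param channel Fluorescence channel name of the editing reporter.
#' @param seed Integer seed.
#' @return A list of class `plate_spec`.
#' @export
plate_spec <- function(pe_ng = c(5, 10, 15, 25, 35, 45, 65, 85),
                       mlh1_ng = c(0, 0.9, 1.5, 2.7, 4.5, 8.4, 15.2, 25.7, 42.8, 59.9, 77),
                       efficiency = function(pe, mlh1)
                         pmin(1, 0.3 * (5 / pe)^0.3 * ((mlh1 + 1) / (mlh1 + 4)) *
                                exp(-mlh1 / 60)),
                       proliferation = function(pe, mlh1) exp(-mlh1 / 20),
                       control_n = 1000,
                       pos_meanlog = log(500), pos_sdlog = 0.5,
                       neg_meanlog = log(10), neg_sdlog = 0.8,
                       channel = "mNG", seed = 1) {
  structure(list(pe_ng = pe_ng, mlh1_ng = mlh1_ng, efficiency = efficiency,
                 proliferation = proliferation, control_n = control_n,
                 pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
                 channel = channel, seed = seed),
            class = "plate_spec")
}

#' Generate a synthetic screen plate with truth surfaces
#'
#' @param spec A [plate_spec()].
#' @return A list of class `screen_plate`: `records` (one row per cell:
#'   `cell_id`, `well`, `condition`, `PE_ng`, `MLH1_ng`, `mean_<channel>`,
#'   `true_positive`; includes the `"no_plasmid"` control well), `truth`
#'   (per-condition tibble with the true efficiency, proliferation and
#'   expected counts), and `spec`.
#' @export
make_screen_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  withr::with_seed(spec$seed, {
    grid <- expand.grid(PE_ng = spec$pe_ng, MLH1_ng = spec$mlh1_ng,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$PE_ng, grid$MLH1_ng), ]
    grid$condition <- sprintf("PE%g_MLH1%g", grid$PE_ng, grid$MLH1_ng)
    grid$well <- paste0(LETTERS[match(grid$PE_ng, spec$pe_ng)],
                        match(grid$MLH1_ng, spec$mlh1_ng))
    eff <- spec$efficiency(grid$PE_ng, grid$MLH1_ng)
    if (any(eff < 0 | eff > 1)) stop_value("efficiency surface must map into [0, 1]")
    prolif <- spec$proliferation(grid$PE_ng, grid$MLH1_ng)
    if (any(prolif < 0)) stop_value("proliferation surface must be >= 0")
    truth <- as_tibble(grid) %>%
      mutate(efficiency = eff, proliferation = prolif,
             expected_n = spec$control_n * prolif)
    mean_col <- paste0("mean_", spec$channel)
    well_records <- function(well, condition, pe, mlh1, n, n_pos) {
      if (n == 0) return(NULL)
      intensity <- c(rlnorm(n_pos, spec$pos_meanlog, spec$pos_sdlog),
                     rlnorm(n - n_pos, spec$neg_meanlog, spec$neg_sdlog))
      out <- tibble(well = well, condition = condition,
                    PE_ng = pe, MLH1_ng = mlh1,
                    true_positive = rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
      out[[mean_col]] <- intensity
      out
    }
    rows <- map(seq_len(nrow(truth)), function(i) {
      n <- rpois(1, truth$expected_n[i])
      n_pos <- if (n > 0) rbinom(1, n, truth$efficiency[i]) else 0L
      well_records(truth$well[i], truth$condition[i],
                   truth$PE_ng[i], truth$MLH1_ng[i], n, n_pos)
    })
    n_ctrl <- rpois(1, spec$control_n)
    rows <- c(rows, list(well_records("CTRL", "no_plasmid",
                                      NA_real_, NA_real_, n_ctrl, 0L)))
    records <- bind_rows(rows)
    records$cell_id <- seq_len(nrow(records))
    records <- records[, c("cell_id", "well", "condition", "PE_ng", "MLH1_ng",
                           mean_col, "true_positive")]
    structure(list(records = records, truth = truth, spec = spec),
              class = "screen_plate")
  })
}
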