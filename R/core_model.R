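#' Build a gene model for the elongation lattice
#'
#' A gene is a one-dimensional lattice of `L` nucleotide sites (site 1 is the
#' transcription start) carrying a fixed set of pause sites and two probe
#' windows. Pause sites are a property of the gene, drawn once from a seed:
#' every elongation complex and every replicate run of the same gene sees the
#' same sites, mimicking sequence-encoded pause signals.
#'
#' @param L Gene length in nucleotides (lattice sites), at least 10.
#' @param pause_density Expected pause sites per nucleotide, in `[0, 0.2]`
#'   (default 0.002: sparse, long-lived pause sites).
#'   The number of pause sites is `round(pause_density * L)`, drawn uniformly
#'   without replacement from sites `2..L-1`.
#' @param seed Integer seed for the pause-site draw; the same
#'   `(L, pause_density, seed)` always yields the identical gene.
#' @param probe_layout Numeric pair of fractions `(early_end, late_start)` of
#'   `L`: the early probe window is `[1, round(early_end * L)]` and the late
#'   window `[round(late_start * L), L]`. The default reproduces a 2700-nt
#'   reporter with windows `[1, 500]` and `[2201, 2700]`.
#' @return An object of class `gene_model`: list with `L`, `pause_sites`
#'   (sorted integer vector), `probe_early`, `probe_late` (start/end pairs)
#'   and `seed`.
#' @examples
#' g <- build_gene(1000, pause_density = 0.005, seed = 1)
#' length(g$pause_sites)  # 5
#' @export
build_gene <- function(L, pause_density = 0.002, seed = 1L,
                       probe_layout = c(500 / 2700, 2201 / 2700)) {
  if (!is.numeric(L) || length(L) != 1L || L < 10)
    stop("L must be a single number >= 10")
  L <- as.integer(round(L))
  if (pause_density < 0 || pause_density > 0.2)
    stop("pause_density must lie in [0, 0.2]")
  n_pause <- as.integer(round(pause_density * L))
  if (n_pause > L - 2L)
    stop("gene too short to host ", n_pause, " pause sites")
  if (length(probe_layout) != 2L || any(probe_layout <= 0) ||
      any(probe_layout > 1) || probe_layout[1] >= probe_layout[2])
    stop("probe_layout must be two increasing fractions in (0, 1]")

  pause_sites <- integer(0)
  if (n_pause > 0L) {
    set.seed(as.integer(seed))
    pause_sites <- sort(sample(2:(L - 1L), n_pause, replace = FALSE))
  }
  probe_early <- c(1L, as.integer(round(probe_layout[1] * L)))
  probe_late <- c(as.integer(round(probe_layout[2] * L)), L)
  if (probe_early[2] >= probe_late[2])
    stop("early probe window must end before the late probe window")

  structure(
    list(L = L, pause_sites = pause_sites,
         probe_early = probe_early, probe_late = probe_late,
         pause_density = pause_density, seed = as.integer(seed)),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> L =", x$L, "nt;", length(x$pause_sites), "pause sites;",
      "probes [", x$probe_early[1], ",", x$probe_early[2], "] / [",
      x$probe_late[1], ",", x$probe_late[2], "]\n")
  invisible(x)
}

#' Kinetic parameters of the elongation model
#'
#' One parameter set describes one simulated condition. Rates follow the
#' stochastic-stepper scheme: complexes enter at the promoter with initiation
#' attempt rate `alpha` when the promoter region is free, step forward with
#' stepping rate `epsilon`, stall at pause sites with rate `f` and are
#' rescued from the stalled state with rate `1/tau`.
#'
#' The fixed timestep `dt` must satisfy
#' `dt * max(alpha, epsilon, f, 1/tau) <= 0.2`; the engine refuses parameter
#' sets outside this regime, where per-step event probabilities stop being
#' small and the discretization degrades.
#'
#' @param alpha Initiation attempt rate (1/s).
#' @param epsilon Stepping (pause-free elongation) rate (nt/s).
#' @param f Stall rate at pause sites (1/s).
#' @param tau Mean stall duration (s); must be positive when `f > 0`.
#' @param footprint Lattice sites occupied by one elongation complex (nt);
#'   enforces hard exclusion at spacing `>= footprint`.
#' @param dt Timestep (s).
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha, epsilon, f = 0, tau = 1,
                           footprint = 35L, dt = 0.01) {
  p <- structure(
    list(alpha = alpha, epsilon = epsilon, f = f, tau = tau,
         footprint = as.integer(footprint), dt = dt),
    class = "kinetic_params")
  validate_params(p)
  p
}

#' Validate a kinetic parameter set
#'
#' Checks non-negativity of the rates, positivity of `tau` (when stalling is
#' possible) and `dt`, `footprint >= 1`, and the timestep-validity guard
#' `dt * max(alpha, epsilon, f, 1/tau) <= 0.2`.
#'
#' @param p A `kinetic_params` object.
#' @return `p`, invisibly; errors otherwise.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  with(p, {
    if (any(c(alpha, epsilon, f) < 0)) stop("rates must be >= 0")
    if (f > 0 && tau <= 0) stop("tau must be > 0 when f > 0")
    if (footprint < 1L) stop("footprint must be >= 1")
    if (dt <= 0) stop("dt must be > 0")
    rmax <- max(alpha, epsilon, f, if (tau > 0) 1 / tau else 0)
    if (dt * rmax > 0.2)
      stop(sprintf(
        "timestep too coarse: dt * max rate = %.3f > 0.2; reduce dt below %.4g s",
        dt * rmax, 0.2 / rmax))
  })
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> alpha=%.4g/s epsilon=%.4g nt/s f=%.4g/s tau=%.4g s d=%d nt dt=%.4g s\n",
    x$alpha, x$epsilon, x$f, x$tau, x$footprint, x$dt))
  invisible(x)
}

.scenario_names <- c("wildtype", "nogre_pause_duration",
                     "nogre_pause_frequency", "nogre_stepping_rate")

#' Define a Gre-factor scenario
#'
#' A scenario expresses one hypothesis for what is lost without the Gre
#' factor: `nogre_pause_duration` multiplies the stall duration `tau` by
#' `factor`, `nogre_pause_frequency` multiplies the stall rate `f`,
#' `nogre_stepping_rate` divides the stepping rate `epsilon`, and `wildtype`
#' changes nothing. Each scenario changes exactly one kinetic field.
#'
#' @param name One of `"wildtype"`, `"nogre_pause_duration"`,
#'   `"nogre_pause_frequency"`, `"nogre_stepping_rate"`.
#' @param factor Positive multiplier.
#' @return Object of class `gre_scenario`.
#' @export
scenario <- function(name, factor = 1) {
  name <- match.arg(name, .scenario_names)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a single positive number")
  structure(list(name = name, factor = factor), class = "gre_scenario")
}

#' Apply a scenario to a kinetic parameter set
#'
#' Returns a new parameter set; the input is never modified. The modified set
#' is re-validated (a scenario can push parameters outside the timestep
#' guard, in which case this errors).
#'
#' @param base A `kinetic_params` object (the wild-type condition).
#' @param s A `gre_scenario`.
#' @return A new `kinetic_params` object.
#' @examples
#' wt <- kinetic_params(alpha = 0.3, epsilon = 62, f = 1, tau = 0.5, dt = 0.003)
#' mut <- apply_scenario(wt, scenario("nogre_pause_duration", 100))
#' mut$tau  # 50
#' @export
apply_scenario <- function(base, s) {
  stopifnot(inherits(base, "kinetic_params"), inherits(s, "gre_scenario"))
  out <- base
  switch(s$name,
    wildtype = NULL,
    nogre_pause_duration = { out$tau <- base$tau * s$factor },
    nogre_pause_frequency = { out$f <- base$f * s$factor },
    nogre_stepping_rate = { out$epsilon <- base$epsilon / s$factor },
    stop("unknown scenario: ", s$name))
  validate_params(out)
  out
}

#' Default kinetic presets for the virtual experiments
#'
#' Returns the package's documented default conditions: a wild-type baseline
#' (2700-nt reporter regime, stepping rate 62 nt/s, short rare pauses) and
#' the three Gre-loss hypotheses. The pause-frequency scenario carries its
#' own wild-type baseline with rare-but-long pauses, the regime that
#' hypothesis requires.
#'
#' @return Named list; each element has `$params` (wild-type baseline) and
#'   `$scenario` (the perturbation to apply for the Gre-less condition).
#' @export
kinetic_presets <- function() {
  base <- kinetic_params(alpha = 0.3, epsilon = 62, f = 4, tau = 0.15,
                         footprint = 35L, dt = 0.003)
  rare_long <- kinetic_params(alpha = 0.3, epsilon = 62, f = 0.15, tau = 40,
                              footprint = 35L, dt = 0.003)
  list(
    wildtype = list(params = base, scenario = scenario("wildtype", 1)),
    nogre_pause_duration = list(
      params = base, scenario = scenario("nogre_pause_duration", 100)),
    nogre_pause_frequency = list(
      params = rare_long, scenario = scenario("nogre_pause_frequency", 5)),
    nogre_stepping_rate = list(
      params = base, scenario = scenario("nogre_stepping_rate", 2)))
}

#' Default reporter gene
#'
#' The 2700-nt virtual reporter used throughout: pause density 0.002/nt
#' (sparse, long-lived pause sites), early probe window `[1, 500]`, late
#' window `[2201, 2700]`.
#'
#' @param seed Seed for the pause-site draw (default fixed so that all
#'   package examples share one construct).
#' @return A `gene_model`.
#' @export
default_gene <- function(seed = 73L) {
  build_gene(2700, pause_density = 0.002, seed = seed)
}

#' Serialize a gene and parameter set to a plain-text config
#'
#' Writes a YAML file with `gene` and `params` blocks that
#' [read_model_config()] restores exactly.
#'
#' @param gene A `gene_model`.
#' @param params A `kinetic_params`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(gene, params, path) {
  stopifnot(inherits(gene, "gene_model"), inherits(params, "kinetic_params"))
  yaml::write_yaml(list(
    gene = list(L = gene$L, pause_density = gene$pause_density,
                seed = gene$seed,
                probe_early = as.integer(gene$probe_early),
                probe_late = as.integer(gene$probe_late),
                pause_sites = as.integer(gene$pause_sites)),
    params = unclass(params)), path)
  invisible(path)
}

#' Read a gene/parameter config written by [write_model_config()]
#'
#' @param path YAML file path.
#' @return List with `$gene` (`gene_model`) and `$params` (`kinetic_params`).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gene <- build_gene(cfg$gene$L, cfg$gene$pause_density, cfg$gene$seed,
                     probe_layout = c(cfg$gene$probe_early[2] / cfg$gene$L,
                                      cfg$gene$probe_late[1] / cfg$gene$L))
  if (!identical(as.integer(gene$pause_sites),
                 as.integer(cfg$gene$pause_sites)))
    stop("stored pause sites do not match the stored (L, density, seed)")
  params <- kinetic_params(cfg$params$alpha, cfg$params$epsilon,
                           cfg$params$f, cfg$params$tau,
                           cfg$params$footprint, cfg$params$dt)
  list(gene = gene, params = params)
}
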