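#' Plasticity configuration
#'
#' Parameters of the neuromodulated Hebbian weight-update rule
#' \eqn{\Delta w_{ij} = \eta \cdot m_i \cdot a_i \cdot a_j} and of the
#' diffusion point-source model that supplies the modulatory signal
#' \eqn{m_i}.
#'
#' @param learning_rate Hebbian learning rate \eqn{\eta} (default 0.002).
#' @param sigma Gaussian falloff width \eqn{\sigma} of the diffusing
#'   signal, in spatial units (default 0.5).
#' @param radius_cutoff distance beyond which a point source has no
#'   effect (default 1.5 units; the comparison is `<=`).
#' @param falloff_normalizer `"planar"` (prefactor
#'   \eqn{e^{-2}/(2\pi\sigma^2)}, the default) or `"linear"`
#'   (\eqn{e^{-2}/(\sigma\sqrt{2\pi})}), selecting the normalisation of
#'   the Gaussian falloff.
#' @param weight_clamp optional symmetric bound; weights are clipped to
#'   `[-weight_clamp, weight_clamp]` after each update (default: none).
#' @param update_pairing which activations enter the Hebbian product when
#'   the one-step-delayed seasonal feedback arrives.  `"eligibility"`
#'   (default) pairs the modulatory signal with the activations of the
#'   presentation that produced the feedback, so credit lands on the
#'   synapses responsible for the outcome; `"concurrent"` pairs it with
#'   the current presentation's activations.  Season boundaries clear the
#'   eligibility.
#' @return an object of class `plasticity_config`.
#' @export
plasticity_config <- function(learning_rate = 0.002,
                              sigma = 0.5,
                              radius_cutoff = 1.5,
                              falloff_normalizer = c("planar", "linear"),
                              weight_clamp = NULL,
                              update_pairing = c("eligibility", "concurrent")) {
  falloff_normalizer <- match.arg(falloff_normalizer)
  update_pairing <- match.arg(update_pairing)
  stopifnot(learning_rate > 0, sigma > 0, radius_cutoff > 0)
  if (!is.null(weight_clamp)) stopifnot(weight_clamp > 0)
  structure(list(learning_rate = learning_rate, sigma = sigma,
                 radius_cutoff = radius_cutoff,
                 falloff_normalizer = falloff_normalizer,
                 weight_clamp = weight_clamp,
                 update_pairing = update_pairing),
            class = "plasticity_config")
}

# prefactor of the Gaussian falloff under the configured normaliser
falloff_prefactor <- function(config) {
  if (config$falloff_normalizer == "planar")
    exp(-2) / (2 * pi * config$sigma^2)
  else
    exp(-2) / (config$sigma * sqrt(2 * pi))
}

#' Gaussian falloff of a diffusing point source
#'
#' Concentration of the simulated modulatory chemical at distance `d`
#' from its point source:
#' \deqn{g(d) = \frac{e^{-2}}{2\pi\sigma^2} e^{-d^2 / (2\sigma^2)}}
#' for \eqn{d \le} `radius_cutoff`, and exactly 0 beyond the cutoff
#' (diffusing neurotransmitters are localised by obstructions and uptake,
#' so the chemical never extends past 1.5 units by default).
#'
#' @param distance non-negative numeric vector of distances.
#' @param config a [plasticity_config()].
#' @return numeric vector of concentrations.
#' @examples
#' gaussian_falloff(0)    # ~0.08616 with the default planar prefactor
#' gaussian_falloff(2)    # 0: beyond the cutoff
#' @export
gaussian_falloff <- function(distance, config = plasticity_config()) {
  if (any(distance < 0)) stop("distance must be non-negative")
  pre <- falloff_prefactor(config)
  out <- pre * exp(-distance^2 / (2 * config$sigma^2))
  out[distance > config$radius_cutoff] <- 0
  out
}

#' Seasonal modulatory point sources
#'
#' The two emitters of the diffusing modulatory chemical, one per season.
#' The summer source sits at (-3, 2) and the winter source at (3, 2); in
#' the default geometry each covers a distinct lateral group of hidden
#' nodes.  A source's `activation` follows its season's feedback: 1 after
#' a nutritious item was eaten, -1 after a poisonous one, 0 when nothing
#' was eaten or out of season.
#'
#' @param summer_xy,winter_xy numeric length-2 positions.
#' @param summer_activation,winter_activation activations in \{-1, 0, 1\}.
#' @return data.frame with columns `season`, `x`, `y`, `activation`.
#' @export
point_sources <- function(summer_xy = c(-3, 2), winter_xy = c(3, 2),
                          summer_activation = 0, winter_activation = 0) {
  data.frame(season = c("summer", "winter"),
             x = c(summer_xy[1], winter_xy[1]),
             y = c(summer_xy[2], winter_xy[2]),
             activation = c(summer_activation, winter_activation))
}

#' Diffusion-based modulatory signal per node
#'
#' For each node i,
#' \eqn{m_i = \phi(a_s g(d_{is}) + a_w g(d_{iw}))}: the steep sigmoid of
#' the summed, distance-attenuated activations of the summer and winter
#' point sources.  Nodes farther than the cutoff from every active source
#' receive exactly 0.
#'
#' @param net a `forage_network`.
#' @param sources a [point_sources()] data.frame.
#' @param config a [plasticity_config()].
#' @return numeric vector of \eqn{m_i} over nodes, in node-id order.
#' @export
diffusion_modulation <- function(net, sources, config = plasticity_config()) {
  stopifnot(nrow(sources) == 2L)
  s <- 0
  for (k in seq_len(nrow(sources))) {
    d <- sqrt((net$nodes$x - sources$x[k])^2 + (net$nodes$y - sources$y[k])^2)
    s <- s + sources$activation[k] * gaussian_falloff(d, config)
  }
  steep_sigmoid(s, net$config$sigmoid_slope)
}

#' Standard (wire-borne) modulatory signal per node
#'
#' Under standard neuromodulation,
#' \eqn{m_i = \phi(\sum_{j \in C_m} w_{ij} a_j)} where \eqn{C_m} are the
#' modulatory in-neighbours of node i.  Nodes without modulatory
#' in-neighbours receive exactly 0.
#'
#' @param net a `forage_network`.
#' @param activations current per-node activations (from [forward_pass()]).
#' @param modul_threshold see [is_modulatory()].
#' @return numeric vector of \eqn{m_i} over nodes.
#' @export
standard_modulation <- function(net, activations, modul_threshold = 0.4) {
  mod <- is_modulatory(net, "standard", modul_threshold)
  m <- numeric(nrow(net$nodes))
  cn <- net$connections
  from_mod <- mod[match(cn$source, net$nodes$id)]
  if (any(from_mod)) {
    cm <- cn[from_mod, , drop = FALSE]
    s <- tapply(cm$weight * activations[match(cm$source, net$nodes$id)],
                factor(cm$target, levels = net$nodes$id), sum, default = NA)
    has <- !is.na(s)
    m[has] <- steep_sigmoid(s[has], net$config$sigmoid_slope)
  }
  m
}

#' Apply one neuromodulated Hebbian learning step
#'
#' Updates every connection feeding into a regular (non-modulatory,
#' non-input) node i by \eqn{\Delta w_{ij} = \eta m_i a_i a_j}.
#' Connections into modulatory nodes are non-plastic.  If
#' `weight_clamp` is set in `config`, weights are clipped afterwards.
#'
#' @param net a `forage_network`.
#' @param modulation per-node modulatory signal \eqn{m_i}
#'   (from [diffusion_modulation()] or [standard_modulation()]).
#' @param activations per-node activations from the preceding
#'   [forward_pass()].
#' @param config a [plasticity_config()].
#' @param treatment `"diffusion"` or `"standard"`.
#' @param modul_threshold see [is_modulatory()].
#' @return the network with updated connection weights.
#' @export
apply_learning_step <- function(net, modulation, activations,
                                config = plasticity_config(),
                                treatment = c("diffusion", "standard"),
                                modul_threshold = 0.4) {
  treatment <- match.arg(treatment)
  mod <- is_modulatory(net, treatment, modul_threshold)
  cn <- net$connections
  ti <- match(cn$target, net$nodes$id)
  si <- match(cn$source, net$nodes$id)
  plastic <- !mod[ti]                 # targets are never input nodes
  dw <- config$learning_rate * modulation[ti] * activations[ti] * activations[si]
  cn$weight[plastic] <- cn$weight[plastic] + dw[plastic]
  if (!is.null(config$weight_clamp))
    cn$weight <- pmin(pmax(cn$weight, -config$weight_clamp), config$weight_clamp)
  net$connections <- cn
  net
}
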