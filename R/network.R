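# The reaction network as data: five reaction equations (reversible
# binding counted as one), realised as six elementary SSA channels.
# Localisation follows the motif: binding/unbinding and transcription in
# the nucleus, translation in the cytoplasm, degradation everywhere.

#' The negative-feedback reaction network
#'
#' Species: `G_free`, `G_bound` (the single gene, free or repressed),
#' `mRNA`, `P`. Channels:
#' \enumerate{
#'   \item `G_free + P -> G_bound` (binding, nucleus), propensity
#'     `k_eff/(NA * V) * G_free * P` with the diffusion-limited effective
#'     rate from [effective_association_rate()];
#'   \item `G_bound -> G_free + P` (unbinding, nucleus), `kd * G_bound`;
#'   \item `G_free -> G_free + mRNA` (transcription, nucleus), `mu * G_free`;
#'   \item `mRNA -> mRNA + P` (translation, cytoplasm), `kappa * mRNA`;
#'   \item `mRNA -> 0` (degradation, entire cell), `gamma * mRNA`;
#'   \item `P -> 0` (degradation, entire cell), `gamma * P`.
#' }
#'
#' @param params a `grn_params` object.
#' @param volume_um3 reaction volume for the bimolecular channel in um^3;
#'   defaults to the whole-cell volume (well-mixed interpretation).
#' @return An object of class `reaction_network`: species, stoichiometry
#'   matrix (species x reactions), propensity closures and localisation
#'   tags.
#' @export
reaction_network <- function(params, volume_um3 = cell_volume_um3(params$R)) {
  stopifnot(inherits(params, "grn_params"))
  species <- c("G_free", "G_bound", "mRNA", "P")
  # stoichiometry: one column per elementary channel
  S <- cbind(
    bind        = c(-1L, +1L, 0L, -1L),
    unbind      = c(+1L, -1L, 0L, +1L),
    transcribe  = c(0L, 0L, +1L, 0L),
    translate   = c(0L, 0L, 0L, +1L),
    degrade_m   = c(0L, 0L, -1L, 0L),
    degrade_p   = c(0L, 0L, 0L, -1L)
  )
  rownames(S) <- species
  kb <- binding_propensity_constant(params, volume_um3)
  propensities <- list(
    bind = function(x) kb * x[["G_free"]] * x[["P"]],
    unbind = function(x) params$kd * x[["G_bound"]],
    transcribe = function(x) params$mu * x[["G_free"]],
    translate = function(x) params$kappa * x[["mRNA"]],
    degrade_m = function(x) params$gamma * x[["mRNA"]],
    degrade_p = function(x) params$gamma * x[["P"]]
  )
  localization <- c(
    bind = "nucleus", unbind = "nucleus", transcribe = "nucleus",
    translate = "cytoplasm", degrade_m = "entire cell", degrade_p = "entire cell"
  )
  structure(
    list(species = species, stoichiometry = S,
         propensities = propensities, localization = localization,
         params = params),
    class = "reaction_network"
  )
}

#' Gene copy conservation of a network's stoichiometry
#'
#' The single gene is conserved: for every reaction channel the net change
#' over the gene species (`G_free` + `G_bound`) is zero.
#'
#' @param network a `reaction_network`.
#' @return `TRUE` if conservation holds for every channel.
#' @export
gene_conserved <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  gene_rows <- c("G_free", "G_bound")
  all(colSums(network$stoichiometry[gene_rows, , drop = FALSE]) == 0L)
}

#' Cell / nucleus volumes
#'
#' @param R radius in um.
#' @return Volume in um^3 (`cell_volume_um3`) or litres (`cell_volume_L`).
#' @export
cell_volume_um3 <- function(R) (4 / 3) * pi * R^3

#' @rdname cell_volume_um3
#' @export
cell_volume_L <- function(R) cell_volume_um3(R) / UM3_PER_L

# Per-pair bimolecular propensity constant (min^-1): k_eff/(NA*V), with V in
# litres; equivalently k_eff in um^3/min divided by the volume in um^3.
binding_propensity_constant <- function(params, volume_um3) {
  if (params$ka <= 0) return(0)  # feedback disabled
  k_eff <- effective_association_rate(params$ka, params$D, reaction_radius(params))
  molar_to_volumetric(k_eff) / volume_um3
}
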