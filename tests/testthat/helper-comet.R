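# Shared fixtures: a tiny catalogue of small molecules (fast to encode),
# small network configurations, and brute-force oracles.

tiny_catalogue <- function() {
  molecule_catalogue(
    id = c("ION-A", "ION-B", "ION-C", "HEL-A", "HEL-B", "STE-A", "STE-B",
           "PEG-A", "PEG-B"),
    smiles = c("CCCCCCCCN(C)CCO", "CCCCCCCCCCN(CC)CCO", "CCCCCCN(CCO)CCN",
               "CCCCCCCC(=O)OCC(O)COP(=O)(O)OCCN", "CCCCCCCCOC(=O)CCN",
               "CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C",
               "CCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C",
               "CCCCCCCC(=O)OCCOCCOCCOC", "CCCCCCCCCC(=O)OCCOCCOCCOC"),
    component_class = c(rep("ionizable", 3), rep("helper", 2),
                        rep("sterol", 2), rep("peg", 2)),
    amine_count = c(1L, 1L, 2L, rep(NA_integer_, 6)),
    molar_mass = c(201.4, 243.4, 216.4, 369.4, 187.3, 386.7, 372.6,
                   274.4, 302.4))
}

tiny_grid <- function(catalogue = tiny_catalogue(), dual = FALSE) {
  by <- split(catalogue$id, catalogue$component_class)
  design_grid(ionizable = by$ionizable, helper = by$helper,
              sterol = by$sterol, peg = by$peg,
              molar_ratios = list(BASE = base_molar_ratio(),
                                  ALT = c(ionizable = 45, helper = 25,
                                          sterol = 27.5, peg = 2.5)),
              np_ratios = c(6, 12), aq_org_ratios = c("3:1", "1:1"),
              dual_ionizable = list(enabled = dual, split = c(60, 40)))
}

# small network: full pipeline, desk-second scale
tiny_cfg <- function(tasks = "t1", seed = 1) {
  comet_config(tasks = tasks, d_token = 32, n_blocks = 1, n_heads = 4,
               mlp_hidden = 48, head_hidden = 16, d_mol = 512, d_comp = 16,
               d_type = 8, np_range = c(0, 20), seed = seed)
}

tiny_labelled_data <- function(n = 120, tasks = "t1", noise_sd = 0.05,
                               seed = 7, catalogue = tiny_catalogue()) {
  grid <- tiny_grid(catalogue, dual = TRUE)
  oc <- oracle_config(catalogue, tasks = tasks, seed = seed)
  generate_dataset(grid, oc, n = n, noise_sd = noise_sd, seed = seed,
                   catalogue = catalogue)
}

# independent brute-force CAGrad oracle: maximize min_i g_i' d over a dense
# grid of directions d with ||d - g0|| <= c ||g0|| (2-d toy problems)
cagrad_brute_force <- function(G, c, n_grid = 200) {
  g0 <- rowMeans(G)
  r <- c * sqrt(sum(g0^2))
  best <- NULL; best_val <- -Inf
  for (ang in seq(0, 2 * pi, length.out = n_grid)) {
    for (rad in seq(0, r, length.out = 50)) {
      d <- g0 + rad * c(cos(ang), sin(ang))
      val <- min(crossprod(G, d))
      if (val > best_val) { best_val <- val; best <- d }
    }
  }
  best
}
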