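# Fixture builders used across the suite.  All cohorts are generated in
# code under fixed seeds.

make_panel <- function(n_species, tribe = "T1", prefix = "sp") {
  sample_panel(data.frame(
    individual_id = paste0(prefix, rep(seq_len(n_species), each = 2L),
                           c("_m", "_f")),
    species_id = paste0(prefix, rep(seq_len(n_species), each = 2L)),
    tribe_id = tribe,
    sex = rep(c("male", "female"), n_species)))
}

make_lgs <- function(n = 3L, len = 1000000L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("LG", sprintf("%02d", 4L + seq_len(n)))
  lg_table(data.frame(lg_id = ids, length_bp = rep(len, length(ids))))
}

# n_carrier species share one planted system, the rest have none
make_truth <- function(n_species, n_carrier, system = "XY",
                       sex_lg = "LG05", region = c(200001L, 500000L),
                       d = 1, prefix = "sp") {
  sim_truth(data.frame(
    species_id = paste0(prefix, seq_len(n_species)),
    sex_lg = c(rep(sex_lg, n_carrier), rep(NA, n_species - n_carrier)),
    system = c(rep(system, n_carrier), rep("none", n_species - n_carrier)),
    region_start = region[1L], region_end = region[2L],
    differentiation = c(rep(d, n_carrier), rep(NA, n_species - n_carrier))))
}

# a bare variant table from a genotype-code matrix (0/1/2/NA)
vt_from_codes <- function(g, panel, lg = "LG01", pos = NULL,
                          ref = NULL, alt = NULL) {
  n <- nrow(g)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  a1 <- ifelse(is.na(g), NA_integer_, ifelse(g == 2L, 1L, 0L))
  a2 <- ifelse(is.na(g), NA_integer_, ifelse(g >= 1L, 1L, 0L))
  sites <- data.frame(lg_id = lg, pos = pos,
                      ref = if (is.null(ref)) rep("A", n) else ref,
                      alt = if (is.null(alt)) rep("G", n) else alt,
                      is_indel = FALSE, indel_size = NA_integer_)
  variant_table(sites, a1, a2,
                matrix(99, n, ncol(g)), matrix(20, n, ncol(g)), panel)
}

ultra_tree <- function(n, height = 10, seed = 1) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * height /
    max(ape::node.depth.edgelength(tr)[seq_len(n)])
  tr
}

# node states realised in a character history (tip + internal), read off
# the edge maps
history_node_states <- function(h) {
  tree <- h$tree
  n_tip <- length(tree$tip.label)
  st <- character(n_tip + tree$Nnode)
  root_edges <- which(tree$edge[, 1L] == n_tip + 1L)
  st[n_tip + 1L] <- names(h$maps[[root_edges[1L]]])[1L]
  for (e in seq_len(nrow(tree$edge))) {
    m <- h$maps[[e]]
    st[tree$edge[e, 2L]] <- names(m)[length(m)]
  }
  st
}
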