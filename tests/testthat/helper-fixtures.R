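# Small shared fixtures, built in code at test time.

small_config <- function(n_plots = 10, n_control = 5, ...) {
  generator_config(n_plots = n_plots, n_control = n_control, ...)
}

small_dataset <- function(seed = 101, n_plots = 10, n_control = 5, ...) {
  gen_dataset(small_config(n_plots, n_control, ...), seed = seed)
}

# hand-built 2-census inventory: 5 trees, one dies, one is removed
toy_inventory <- function() {
  data.frame(
    plot_id = "A",
    census_date = rep(c(1970.0, 1972.5), each = 5),
    tree_id = rep(paste0("t", 1:5), 2),
    dbh = c(10, 12, 14, 16, 18, 10.5, 12.8, 14.9, 17.1, 19.2),
    status = c(rep("alive", 5), "dead", "alive", "removed", "alive", "alive"),
    species = "E_regnans",
    stringsAsFactors = FALSE)
}

toy_meta <- function() {
  data.frame(plot_id = "A", area_m2 = 1000, disturbed = FALSE,
             stringsAsFactors = FALSE)
}
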