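# The synthetic study panel is generated once per test run (seeded) and
# the full pipeline run over it is cached; recovery and acceptance tests
# all read from this shared fixture.

.panel_cache <- new.env(parent = emptyenv())

shared_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    dir <- file.path(tempdir(), "panelomics-shared-panel")
    unlink(dir, recursive = TRUE)
    .panel_cache$panel <- generate_panel(panel_spec(seed = 42L), dir)
  }
  .panel_cache$panel
}

shared_report <- function() {
  if (is.null(.panel_cache$report)) {
    p <- shared_panel()
    .panel_cache$report <- run_panel(
      p$dir, out_dir = file.path(p$dir, "results"))
  }
  .panel_cache$report
}
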