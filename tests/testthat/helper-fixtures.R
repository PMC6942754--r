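# Shared fixtures, built lazily and cached for the whole test run.  The
# expensive objects (meshes, full coupled simulations) are reused across
# test files; everything is deterministic so sharing is safe.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- suppressWarnings(build())
  .fx[[name]]
}

fx_params <- function() fx("params", default_params)

# CNT-free cell scene and default mesh
fx_cell_mesh <- function() fx("cell_mesh", function() {
  build_mesh(build_scene(fx_params(), seed = 0L))
})

# seed-42 CNT scene and mesh
fx_cnt_scene <- function() fx("cnt_scene", function() {
  p <- fx_params()
  build_scene(p, sample_cnts(p, seed = 42), seed = 42L)
})
fx_cnt_mesh <- function() fx("cnt_mesh", function() build_mesh(fx_cnt_scene()))

# full coupled baseline (CNT-free) and CNT runs to t_end
fx_baseline_sim <- function() fx("baseline_sim", function() {
  p <- fx_params()
  run_simulation(p, build_scene(p, seed = 0L), fx_cell_mesh())
})
fx_cnt_sim <- function() fx("cnt_sim", function() {
  run_simulation(fx_params(), fx_cnt_scene(), fx_cnt_mesh())
})

# passive (no electroporation, insulating membrane) charging run on a large
# domain: the 2D Schwan benchmark
fx_schwan_sim <- function() fx("schwan_sim", function() {
  p <- params_from_list(list(
    sigma_mem = 0, side = "400 um", t_rise = "2 ns", t_width = "4000 ns",
    t_end = "4002 ns", dt_coarse = "20 ns", snapshot_every = "400 ns"))
  sc <- build_scene(p, seed = 0L)
  run_simulation(p, sc, build_mesh(sc, h_far = 20e-6), ep = FALSE,
                 t_stop = 3400e-9)
})

# closed polygon (matrix) for a circle
circle_polygon <- function(center, r, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
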