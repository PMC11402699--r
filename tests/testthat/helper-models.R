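# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small noiseless phantom (0.5 mm voxels) -- fast imaging-stage fixture
small_phantom_spec <- function(...) {
  args <- utils::modifyList(list(voxel_size = 0.5, noise_sd = 0), list(...))
  do.call(phantom_spec, args)
}

small_phantom <- function() {
  fixture("small_phantom", function() make_phalanx_phantom(small_phantom_spec()))
}

# coarse plate--bone model driven by the standard flexion-scale motion
small_config <- function() {
  cfg <- pipeline_config()
  cfg$phantom <- list(voxel_size = 0.5, noise_sd = 0)
  cfg$registration$enabled <- FALSE
  cfg
}

small_model <- function() {
  fixture("small_model", function() {
    build_phantom_model(small_phantom_spec(), plate_spec(), small_config(),
                        register = FALSE)
  })
}

flexion_transform <- function(model, angle_deg = 2,
                              translation = c(0, -0.1, 0)) {
  rigid_transform(rotation_from_axis_angle(c(0, 0, 1), angle_deg * pi / 180),
                  translation, origin = model$divots[2, ])
}

# slender all-PEEK cantilever (20 x 1 x 1 mm at 0.25 mm edge)
cantilever_fixture <- function() {
  fixture("cantilever", function() {
    f <- 0.25; L <- 20
    cubes <- as.matrix(expand.grid(0:(L / f - 1), 0:(1 / f - 1),
                                   0:(1 / f - 1)))
    mesh <- cubes_to_tet10(cubes, f, E = 1740.5, nu = 0.3779)
    x <- mesh$nodes[, 1]
    list(mesh = mesh, system = build_system(mesh), L = L,
         E = 1740.5, I = 1 / 12,
         clamp = which(x < 1e-9), tip = which(x > L - 1e-9))
  })
}

# deflect the cantilever tip transversely (uy prescribed on the tip face
# only, leaving the tip section free to rotate -> Euler-Bernoulli end load)
cantilever_solution <- function(delta = 1) {
  fixture(paste0("cantilever_sol_", delta), function() {
    cb <- cantilever_fixture()
    pd <- c(as.vector(t(cbind(3 * (cb$clamp - 1) + 1, 3 * (cb$clamp - 1) + 2,
                              3 * (cb$clamp - 1) + 3))),
            3 * (cb$tip - 1) + 2)
    pv <- c(rep(0, 3 * length(cb$clamp)), rep(delta, length(cb$tip)))
    sol <- solve_linear_system(cb$system, pd, pv)
    c(cb, list(sol = sol, delta = delta))
  })
}

dof_of <- function(nodes, axis) 3L * (nodes - 1L) + axis
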