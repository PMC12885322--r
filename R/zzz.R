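.fluxweaver <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  # reticulate discovers python lazily; pin it to the interpreter on PATH so
  # that the scipy in the active environment is used without any configuration.
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python")
    if (nzchar(py)) Sys.setenv(RETICULATE_PYTHON = py)
  }
  invisible()
}

scipy_optimize <- function() {
  if (is.null(.fluxweaver$scipy_opt)) {
    .fluxweaver$scipy_opt <- reticulate::import("scipy.optimize", delay_load = FALSE)
    .fluxweaver$scipy_version <- as.character(
      reticulate::import("scipy")$`__version__`
    )
  }
  .fluxweaver$scipy_opt
}

solver_backend_info <- function() {
  scipy_optimize()
  list(backend = "HiGHS (scipy.optimize.milp)", scipy = .fluxweaver$scipy_version)
}
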