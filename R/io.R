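# JSON serialisation of fit results and run manifests.

#' Write a fitted model to JSON
#'
#' Serialises parameters, posteriors, likelihood values and convergence
#' metadata.  Given the same fit, the file content is byte-identical.
#'
#' @param fit a [pofm_fit()] result.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "pofm_fit"))
  obj <- list(
    spec = fit$spec[!vapply(fit$spec, is.null, logical(1))],
    params = fit$params[!vapply(fit$params, is.null, logical(1))],
    posteriors = list(zhat = fit$posteriors$zhat,
                      xhat = fit$posteriors$xhat),
    loglik = fit$loglik, loglik_flag = fit$loglik_flag,
    loglik_complete = fit$loglik_complete, entropy = fit$entropy,
    nu = fit$nu, n_iter = fit$n_iter, converged = fit$converged,
    seed = fit$seed, trace = fit$trace,
    n = fit$n, p = fit$p, q = fit$q)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

# manifest describing one reproducible run (seeds, options, input digests)
run_manifest <- function(command, options, seed, inputs = character(),
                         started = NULL, finished = NULL) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  list(command = command, options = options, seed = seed,
       input_md5 = digests,
       package = "pofm",
       version = as.character(utils::packageVersion("pofm")),
       started = started, finished = finished)
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
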