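# Plain-text interchange: traces as two-column CSV with a JSON protocol
# sidecar; training datasets as paired CSVs with a JSON metadata sidecar;
# trained generators as a JSON bundle.

#' Read and write voltage traces
#'
#' A trace is stored as a two-column CSV (\code{t_ms}, \code{V_mV}) with the
#' stimulus protocol in a JSON sidecar at \code{<path>.json}.
#'
#' @param trace A \code{ca1_trace}.
#' @param path CSV file path.
#' @return \code{write_trace_csv()} returns \code{path} invisibly;
#'   \code{read_trace_csv()} returns a \code{ca1_trace}.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(t_ms = trace$t, V_mV = trace$V), path)
  p <- attr(trace, "protocol")
  jsonlite::write_json(unclass(p), paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  pj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  proto <- do.call(stim_protocol, pj[setdiff(names(pj), "bias_current")])
  proto$bias_current <- pj$bias_current
  out <- tibble::tibble(t = d$t_ms, V = d$V_mV)
  structure(out, protocol = proto, class = c("ca1_trace", class(out)))
}

#' Read and write training datasets
#'
#' Parameters and features are written as \code{<stem>_params.csv} and
#' \code{<stem>_features.csv}; discard counts, normalization metadata,
#' bounds and seed go to \code{<stem>_meta.json}.
#'
#' @param dataset A \code{ganpop_training} dataset.
#' @param stem File-path stem (no extension).
#' @return \code{write_training_dataset()} returns \code{stem} invisibly;
#'   \code{read_training_dataset()} returns the dataset.
#' @export
write_training_dataset <- function(dataset, stem) {
  readr::write_csv(dataset$params, paste0(stem, "_params.csv"))
  readr::write_csv(dataset$features, paste0(stem, "_features.csv"))
  meta <- list(discarded = dataset$discarded,
               n_attempted = dataset$n_attempted,
               normalization = purrr::map(dataset$normalization, as.list),
               bounds = dataset$bounds, seed = dataset$seed)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_training_dataset
#' @export
read_training_dataset <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  norm <- purrr::map(meta$normalization, ~ unlist(.x))
  structure(
    list(params = readr::read_csv(paste0(stem, "_params.csv"),
                                  show_col_types = FALSE),
         features = readr::read_csv(paste0(stem, "_features.csv"),
                                    show_col_types = FALSE),
         discarded = meta$discarded, n_attempted = meta$n_attempted,
         normalization = norm,
         bounds = tibble::as_tibble(meta$bounds), seed = meta$seed),
    class = "ganpop_training")
}

#' Save and load a trained generator bundle
#'
#' The selected generator weights, normalization metadata, logs and
#' configuration are serialized to a single JSON file (text-only bundle).
#'
#' @param model A \code{ganpop_cgan}.
#' @param path JSON file path.
#' @return \code{save_cgan()} returns \code{path} invisibly;
#'   \code{load_cgan()} returns the model (without the unselected final
#'   weights' optimizer state).
#' @export
save_cgan <- function(model, path) {
  ser_net <- function(net) {
    list(W = purrr::map(net$W, function(w) list(nrow = nrow(w),
                                                ncol = ncol(w),
                                                v = as.numeric(w))),
         b = net$b, out = net$out)
  }
  norm <- model$normalization
  plain <- setdiff(names(norm), "feature_quantiles")
  norm[plain] <- purrr::map(norm[plain], as.list)
  obj <- list(
    generator = ser_net(model$generator),
    final_generator = ser_net(model$final_generator),
    selected_iteration = model$selected_iteration,
    selected_jsd = model$selected_jsd,
    log = model$log, jsd_log = model$jsd_log,
    normalization = norm,
    param_names = model$param_names,
    feature_names = model$feature_names,
    config = unclass(model$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cgan
#' @export
load_cgan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_net <- function(s) {
    list(W = purrr::map(s$W, function(w) {
           matrix(unlist(w$v), w$nrow, w$ncol)
         }),
         b = purrr::map(s$b, ~ unlist(.x)),
         out = as.character(unlist(s$out)))
  }
  cfg <- structure(purrr::map(obj$config, ~ unlist(.x)), class = "gan_config")
  norm <- obj$normalization
  plain <- setdiff(names(norm), "feature_quantiles")
  norm[plain] <- purrr::map(norm[plain], ~ unlist(.x))
  if (!is.null(norm$feature_quantiles)) {
    norm$feature_quantiles <- purrr::map(norm$feature_quantiles,
                                         function(qp) list(q = unlist(qp$q),
                                                           p = unlist(qp$p)))
  }
  as_tbl <- function(x) {
    tibble::as_tibble(purrr::map(purrr::transpose(x), ~ unlist(.x)))
  }
  structure(
    list(generator = de_net(obj$generator),
         final_generator = de_net(obj$final_generator),
         selected_iteration = obj$selected_iteration,
         selected_jsd = obj$selected_jsd,
         log = as_tbl(obj$log),
         jsd_log = as_tbl(obj$jsd_log),
         normalization = norm,
         param_names = unlist(obj$param_names),
         feature_names = unlist(obj$feature_names),
         config = cfg),
    class = "ganpop_cgan")
}
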