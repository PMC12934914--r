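#' Write a network to JSON
#'
#' Serializes nodes, the weight matrix (row-major), the selected penalty,
#' EBIC and sample size; [read_network()] restores the `ggm_network`.
#'
#' @param net a `ggm_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(nodes = net$nodes,
              weights = as.numeric(t(net$weights)),
              lambda = net$lambda_selected, ebic = net$ebic, n = net$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path file written by [write_network()].
#' @return a `ggm_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$nodes)
  W <- matrix(obj$weights, p, p, byrow = TRUE,
              dimnames = list(obj$nodes, obj$nodes))
  new_ggm_network(obj$nodes, W, obj$lambda, obj$ebic, obj$n)
}

#' Write a community partition to JSON
#'
#' @param partition a `community_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  obj <- list(assignment = as.list(partition$assignment),
              labels = as.list(partition$labels),
              modularity = partition$modularity)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a community partition from JSON
#'
#' @param path file written by [write_partition()].
#' @return a `community_partition`.
#' @export
read_partition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(assignment = unlist(obj$assignment),
                 labels = stats::setNames(unlist(obj$labels),
                                          names(obj$labels)),
                 modularity = obj$modularity),
            class = "community_partition")
}

#' Write a trial state to a long-format CSV
#'
#' One row per participant and time point with columns `participant`,
#' `stratum`, `arm`, `time` (`T0`/`T1`) and the 30 item columns.
#'
#' @param trial a `trial_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  base <- data.frame(participant = seq_len(nrow(trial$t0)),
                     stratum = trial$stratum,
                     arm = as.character(trial$arm),
                     stringsAsFactors = FALSE)
  long <- rbind(cbind(base, time = "T0", as.data.frame(trial$t0)),
                cbind(base, time = "T1", as.data.frame(trial$t1)))
  long <- long[order(long$participant, long$time), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
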