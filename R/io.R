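#' Read / write an extraction state
#'
#' States are stored as TSV `agent_id<TAB>source_id<TAB>q` with 0-based ids
#' and 17 significant digits, so round trips are lossless; a JSON sidecar
#' (`<path>.json`) records the game parameters when supplied.
#'
#' @param q state vector aligned with `net$edges`.
#' @param net a [bipartite_network()].
#' @param path file path.
#' @param params optional [game_params()] written to the sidecar.
#' @return `write_state()` returns `path` invisibly; `read_state()` returns
#'   the state vector (sidecar parameters, if present, attached as attribute
#'   `params`).
#' @export
write_state <- function(q, net, path, params = NULL) {
  q <- check_state(q, net)
  df <- data.frame(agent_id = net$edges[, 1] - 1L,
                   source_id = net$edges[, 2] - 1L,
                   q = sprintf("%.17g", q))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(unclass(params), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path, net) {
  df <- read.delim(path, colClasses = c("integer", "integer", "numeric"))
  key_file <- paste(df$agent_id + 1L, df$source_id + 1L)
  key_net <- paste(net$edges[, 1], net$edges[, 2])
  idx <- match(key_net, key_file)
  if (anyNA(idx)) stop("state file does not cover every network edge")
  q <- df$q[idx]
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(q, "params") <- jsonlite::read_json(side, simplifyVector = TRUE)
  check_state(as.numeric(q), net)
  q
}
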