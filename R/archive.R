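#' Save a model to a plain-text archive
#'
#' Writes a single text file with a JSON configuration header followed by
#' tab-separated blocks: anchor motifs, anchor positions, and the dense
#' fully-connected weights and biases. The format is human-readable and
#' round-trips through [load_model()] at full double precision.
#'
#' @param model A `pam_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  header <- list(
    format = "pamnet-model-1",
    kind = model$kind, alphabet_size = model$alphabet_size,
    L = model$L, L_out = model$L_out,
    k = cfg$pam$k, alpha = cfg$pam$alpha, beta = cfg$pam$beta,
    sigma = cfg$pam$sigma,
    n_anchors = cfg$n_anchors, hidden_units = cfg$hidden_units,
    n_classes = cfg$n_classes, epochs = cfg$epochs,
    learning_rate = cfg$learning_rate, seed = cfg$seed,
    train_positions = cfg$train_positions, epsilon = cfg$epsilon,
    optimizer = cfg$optimizer, loss = cfg$loss,
    weight_decay = cfg$weight_decay,
    training_log = model$training_log
  )
  writeLines(paste0("#CONFIG\t", jsonlite::toJSON(header, auto_unbox = TRUE,
                                                  digits = NA)), con)
  blocks <- list(ANCHOR_MOTIFS = model$anchors$motifs,
                 ANCHOR_POSITIONS = model$anchors$positions,
                 W1 = model$W1, B1 = matrix(model$b1, nrow = 1),
                 W2 = model$W2, B2 = matrix(model$b2, nrow = 1))
  for (name in names(blocks)) {
    m <- blocks[[name]]
    writeLines(sprintf("#%s\t%d\t%d", name, nrow(m), ncol(m)), con)
    body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Load a model from a plain-text archive
#'
#' @param path File written by [save_model()].
#' @return A `pam_model` ready for [predict.pam_model()] and the
#'   interpretation functions.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#CONFIG\t")) stop("not a pamnet model archive")
  header <- jsonlite::fromJSON(sub("^#CONFIG\t", "", lines[1]))
  blocks <- list()
  i <- 2L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "\t")[[1]]
    name <- sub("^#", "", parts[1])
    nr <- as.integer(parts[2]); nc <- as.integer(parts[3])
    body <- lines[i + seq_len(nr)]
    blocks[[name]] <- matrix(as.numeric(unlist(strsplit(body, "\t"))),
                             nrow = nr, ncol = nc, byrow = TRUE)
    i <- i + nr + 1L
  }
  params <- pam_params(k = header$k, alpha = header$alpha, beta = header$beta,
                       sigma = header$sigma)
  config <- pam_config(params, n_anchors = header$n_anchors,
                       hidden_units = header$hidden_units,
                       n_classes = header$n_classes, epochs = header$epochs,
                       learning_rate = header$learning_rate,
                       seed = header$seed,
                       train_positions = header$train_positions,
                       epsilon = header$epsilon,
                       optimizer = if (is.null(header$optimizer)) "adam"
                                   else header$optimizer,
                       loss = header$loss,
                       weight_decay = header$weight_decay)
  anchors <- structure(
    list(n = header$n_anchors, motifs = blocks$ANCHOR_MOTIFS,
         positions = blocks$ANCHOR_POSITIONS,
         alphabet_size = header$alphabet_size, k = header$k,
         trainable = FALSE),
    class = "anchor_set")
  state <- gram_inverse_sqrt(anchors, params, header$epsilon)
  structure(list(config = config, anchors = anchors, nystrom = state,
                 W1 = blocks$W1, b1 = drop(blocks$B1),
                 W2 = blocks$W2, b2 = drop(blocks$B2),
                 L = header$L, L_out = header$L_out,
                 alphabet_size = header$alphabet_size, kind = header$kind,
                 training_log = as.numeric(header$training_log)),
            class = "pam_model")
}
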