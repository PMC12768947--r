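#' CNN architecture configuration
#'
#' Describes a 1D convolutional network of stacked conv/ReLU/max-pool blocks
#' followed by one dense layer and a task head. The default — three blocks
#' with 16/32/64 filters, kernel width 9, pool width 2, a 64-unit dense
#' layer and dropout 0.2 — is shared by the classifier and regressor; only
#' the head differs (5 independent sigmoids for multilabel presence, 6
#' unconstrained outputs for the contribution + normalization regression).
#'
#' @param conv_blocks list of blocks, each a list/vector with `filters`,
#'   `kernel` (odd) and `pool`.
#' @param dense_units width of the dense layer.
#' @param dropout dropout fraction on the dense layer, in `[0, 1)`.
#' @param head `"classifier"` or `"regressor"`.
#' @return An object of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_blocks = list(c(16, 9, 2), c(32, 9, 2),
                                                c(64, 9, 2)),
                             dense_units = 64L, dropout = 0.2,
                             head = c("classifier", "regressor")) {
  head <- match.arg(head)
  conv_blocks <- lapply(conv_blocks, function(b) {
    b <- as.integer(unlist(b))
    if (length(b) != 3L) stop("cnn_architecture: block needs (filters, kernel, pool)")
    if (b[2L] %% 2L == 0L) stop("cnn_architecture: kernel width must be odd")
    if (any(b < 1L)) stop("cnn_architecture: block entries must be positive")
    list(filters = b[1L], kernel = b[2L], pool = b[3L])
  })
  if (dropout < 0 || dropout >= 1)
    stop("cnn_architecture: dropout must be in [0, 1)")
  structure(list(conv_blocks = conv_blocks,
                 dense_units = as.integer(dense_units),
                 dropout = dropout, head = head),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  blks <- vapply(x$conv_blocks, function(b)
    sprintf("conv(%d,k%d)/pool%d", b$filters, b$kernel, b$pool), character(1))
  cat(sprintf("<cnn_architecture> %s head: %s -> dense(%d, dropout %.2f) -> %d outputs\n",
              x$head, paste(blks, collapse = " -> "), x$dense_units,
              x$dropout, if (x$head == "classifier") 5L else 6L))
  invisible(x)
}

#' Training configuration
#'
#' @param max_epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_epochs = 10L, batch_size = 64L,
                            learning_rate = 1e-3, patience = 8L,
                            seed = 1L) {
  if (max_epochs < 1 || batch_size < 1 || learning_rate <= 0 || patience < 1)
    stop("training_config: all settings must be positive")
  if (patience >= max_epochs)
    stop("training_config: patience must be below max_epochs")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

#' Build an (untrained) 1D CNN
#'
#' Initialises all parameters (He-normal, seeded) for the given architecture
#' and input length. The classifier head produces 5 values in `[0, 1]`
#' (independent sigmoids, one per target); the regressor head produces 6
#' unconstrained values (five contributions plus the normalization factor).
#'
#' @param arch a [cnn_architecture()].
#' @param input_length spectrum length the network accepts (default 660).
#' @param seed seed for weight initialisation.
#' @return An object of class `sers_cnn` (untrained).
#' @export
build_cnn <- function(arch = cnn_architecture(), input_length = 660L,
                      seed = 1L) {
  stopifnot(inherits(arch, "cnn_architecture"))
  input_length <- as.integer(input_length)
  cnn_layer_sizes(arch, input_length)  # validates feasibility
  set.seed(seed)
  structure(list(architecture = arch, input_length = input_length,
                 params = cnn_init_params(arch, input_length),
                 trained = FALSE, history = NULL, seed = as.integer(seed)),
            class = "sers_cnn")
}

# labels for a head from a sim_dataset or an explicit matrix
cnn_labels <- function(data, head) {
  if (inherits(data, "sim_dataset")) {
    if (head == "classifier") return(matrix(as.numeric(data$presence),
                                            nrow(data$presence)))
    return(cbind(data$contributions, data$norm_factor))
  }
  y <- data$y
  want <- if (head == "classifier") 5L else 6L
  if (is.null(y) || ncol(y) != want)
    stop(sprintf("cnn: %s head needs %d label columns, got %s",
                 head, want, if (is.null(y)) "none" else ncol(y)))
  y
}

cnn_inputs <- function(data) {
  if (inherits(data, "sim_dataset")) return(data$x)
  if (is.matrix(data)) return(data)
  if (!is.null(data$x)) return(data$x)
  stop("cnn: cannot extract an input matrix from the supplied data")
}

#' Train a CNN on simulated datasets
#'
#' Minibatch Adam on multilabel binary cross-entropy (classifier) or mean
#' squared error over the 6-vector (regressor), with early stopping on the
#' validation loss: the weights returned are those of the best validation
#' epoch, never worse.
#'
#' @param model an untrained or trained [build_cnn()] object.
#' @param train_set,val_set `sim_dataset` objects (or lists with `x`, `y`).
#' @param config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return The trained `sers_cnn`, with `$history` (per-epoch train/val
#'   loss) and `$trained = TRUE`.
#' @export
train_cnn <- function(model, train_set, val_set,
                      config = training_config(), verbose = FALSE) {
  stopifnot(inherits(model, "sers_cnn"))
  arch <- model$architecture
  X <- cnn_inputs(train_set); Y <- cnn_labels(train_set, arch$head)
  Xv <- cnn_inputs(val_set);  Yv <- cnn_labels(val_set, arch$head)
  if (ncol(X) != model$input_length)
    stop("train_cnn: dataset spectrum length does not match model input")
  set.seed(config$seed)
  params <- model$params
  state <- adam_init(params)
  n <- nrow(X)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- cnn_forward(params, arch, X[sel, , drop = FALSE], cache = TRUE,
                         dropout_active = TRUE)
      l <- if (arch$head == "classifier")
        bce_loss(fwd$out, Y[sel, , drop = FALSE])
      else mse_loss(fwd$out, Y[sel, , drop = FALSE])
      grads <- cnn_backward(params, arch, fwd, l$dO)
      st <- adam_step(params, grads, state, config$learning_rate)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + l$loss * length(sel)
    }
    val_loss <- cnn_dataset_loss(params, arch, Xv, Yv)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", epoch,
                      ep_loss / n, val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model$trained <- TRUE
  model$training_config <- config
  model
}

#' Predict scores for spectra
#'
#' Runs the forward pass over a matrix of unit-max spectra (rows), a
#' `sim_dataset`, or a [spectrum_set()]. Classifier scores are sigmoid
#' probabilities in `[0, 1]`; regressor outputs are the raw 6-vector.
#'
#' @param object a trained `sers_cnn`.
#' @param newdata input spectra.
#' @param check_trained error on untrained models (set `FALSE` to probe the
#'   initial forward pass of a freshly built network).
#' @param ... unused.
#' @return An `n x 5` (classifier) or `n x 6` (regressor) score matrix.
#' @export
predict.sers_cnn <- function(object, newdata, check_trained = TRUE, ...) {
  if (check_trained && !object$trained)
    stop("predict.sers_cnn: model is untrained")
  X <- if (inherits(newdata, "spectrum_set")) set_matrix(newdata)
       else if (inherits(newdata, "spectrum_1d"))
         matrix(newdata$intensities, 1L)
       else cnn_inputs(newdata)
  if (ncol(X) != object$input_length)
    stop("predict.sers_cnn: input length mismatch")
  O <- matrix(0, nrow(X), if (object$architecture$head == "classifier") 5L else 6L)
  for (start in seq(1L, nrow(X), by = 512L)) {
    sel <- start:min(start + 511L, nrow(X))
    O[sel, ] <- cnn_forward(object$params, object$architecture,
                            X[sel, , drop = FALSE])
  }
  if (object$architecture$head == "classifier") O <- sigmoid(O)
  O
}

#' @rdname predict.sers_cnn
#' @param model a trained `sers_cnn`.
#' @param spectra input spectra (matrix, `sim_dataset` or [spectrum_set()]).
#' @export
predict_scores <- function(model, spectra) predict(model, spectra)

#' @export
print.sers_cnn <- function(x, ...) {
  cat(sprintf("<sers_cnn> %s, input length %d, %s\n",
              x$architecture$head, x$input_length,
              if (x$trained) sprintf("trained (best epoch %d, val loss %.5g)",
                                     x$best_epoch, x$best_val_loss)
              else "untrained"))
  print(x$architecture)
  invisible(x)
}

#' @export
summary.sers_cnn <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("training history (last rows):\n")
    print(utils::tail(object$history, 5L))
  }
  np <- sum(vapply(object$params$conv, function(p) length(p$W) + length(p$b),
                   numeric(1))) +
    length(object$params$dense$W) + length(object$params$dense$b) +
    length(object$params$out$W) + length(object$params$out$b)
  cat(sprintf("parameters: %d\n", as.integer(np)))
  invisible(object)
}

#' @export
plot.sers_cnn <- function(x, ...) {
  if (!x$trained) stop("plot.sers_cnn: nothing to plot for untrained model")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss",
                    main = sprintf("%s training history", x$architecture$head))
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Random architecture search on the optimization set
#'
#' Samples `n_trials` architectures from a bounded space, trains each
#' briefly on an 80/20 split of the optimization dataset, and returns the
#' configuration with the lowest held-out loss. Fully deterministic given
#' `seed`.
#'
#' @param space named list of candidate vectors: `filters_base` (first-block
#'   filter count; later blocks double it per block), `kernel`, `pool`,
#'   `dense_units`, `dropout`. Missing entries fall back to the defaults.
#' @param opt_set `sim_dataset` used for the search.
#' @param n_trials number of random draws (>= 1).
#' @param head model head being tuned.
#' @param seed RNG seed.
#' @param epochs brief training budget per trial.
#' @return The best [cnn_architecture()]; the scored trial table is attached
#'   as attribute `"trials"`.
#' @export
search_architecture <- function(space = list(), opt_set, n_trials = 5L,
                                head = c("classifier", "regressor"),
                                seed = 1L, epochs = 3L) {
  head <- match.arg(head)
  if (n_trials < 1L) stop("search_architecture: n_trials must be >= 1")
  defaults <- list(filters_base = 16L, kernel = 9L, pool = 2L,
                   dense_units = 64L, dropout = 0.2)
  for (nm in names(defaults))
    if (is.null(space[[nm]])) space[[nm]] <- defaults[[nm]]
  bad <- vapply(space, function(v) length(v) < 1L, logical(1))
  if (any(bad)) stop("search_architecture: empty candidate set for ",
                     paste(names(space)[bad], collapse = ", "))
  set.seed(seed)
  n <- nrow(opt_set$x)
  ho <- sample.int(n, max(1L, round(0.2 * n)))
  tr_idx <- setdiff(seq_len(n), ho)
  sub <- function(idx) list(x = opt_set$x[idx, , drop = FALSE],
                            y = cnn_labels(opt_set, head)[idx, , drop = FALSE])
  tr <- sub(tr_idx); hv <- sub(ho)
  pick <- function(v) v[[sample.int(length(v), 1L)]]
  trials <- data.frame()
  best <- NULL; best_loss <- Inf
  for (t in seq_len(n_trials)) {
    fb <- pick(space$filters_base); kk <- pick(space$kernel)
    pp <- pick(space$pool); du <- pick(space$dense_units)
    dr <- pick(space$dropout)
    arch <- cnn_architecture(list(c(fb, kk, pp), c(2L * fb, kk, pp),
                                  c(4L * fb, kk, pp)),
                             dense_units = du, dropout = dr, head = head)
    m <- build_cnn(arch, ncol(opt_set$x), seed = seed + t)
    cfg <- training_config(max_epochs = max(2L, epochs),
                           patience = max(1L, epochs - 1L), seed = seed + t)
    m <- train_cnn(m, tr, hv, cfg)
    loss <- m$best_val_loss
    trials <- rbind(trials, data.frame(trial = t, filters_base = fb,
                                       kernel = kk, pool = pp,
                                       dense_units = du, dropout = dr,
                                       holdout_loss = loss))
    if (loss < best_loss) { best_loss <- loss; best <- arch }
  }
  attr(best, "trials") <- trials
  best
}
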