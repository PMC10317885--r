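#' Build a 5-fold cross-validation plan at patient level
#'
#' Patients are shuffled by `seed` and partitioned into 5 equally sized test
#' folds; for each fold, the remaining 80% is split 4:1 into training and
#' validation (64% / 16% of the total). Splits are at patient level — all
#' patches of a patient stay on one side — so no patient leaks between the
#' training and test data of a fold.
#'
#' @param patient_ids vector of unique patient identifiers, length >= 5.
#' @param seed integer shuffle seed.
#' @param n_folds number of folds (default 5).
#' @return An object of class `fold_plan`: a list of folds, each with
#'   `test`, `train`, and `validation` id vectors.
#' @export
make_folds <- function(patient_ids, seed, n_folds = 5L) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  if (n < n_folds) stop("need at least ", n_folds, " patients")
  shuffled <- withr::with_seed(seed, sample(patient_ids))
  # contiguous, near-equal chunks of the shuffled order
  sizes <- diff(round(seq(0, n, length.out = n_folds + 1)))
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  folds <- lapply(seq_len(n_folds), function(k) {
    test <- shuffled[starts[k]:stops[k]]
    rest <- shuffled[-(starts[k]:stops[k])]
    n_val <- round(length(rest) / 5)
    list(test = test,
         train = rest[seq_len(length(rest) - n_val)],
         validation = rest[length(rest) - n_val + seq_len(n_val)])
  })
  structure(folds, class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds\n", length(x)))
  for (k in seq_along(x)) {
    cat(sprintf("  fold %d: %d train / %d validation / %d test\n", k,
                length(x[[k]]$train), length(x[[k]]$validation),
                length(x[[k]]$test)))
  }
  invisible(x)
}

adadelta_init <- function(n) list(eg2 = numeric(n), edx2 = numeric(n))

adadelta_step <- function(theta, grad, state, lr = 1, rho = 0.9, eps = 1e-6) {
  state$eg2 <- rho * state$eg2 + (1 - rho) * grad^2
  dx <- -sqrt(state$edx2 + eps) / sqrt(state$eg2 + eps) * grad * lr
  state$edx2 <- rho * state$edx2 + (1 - rho) * dx^2
  list(theta = theta + dx, state = state)
}

sample_to_input <- function(s) {
  rbind(as.numeric(s$pet), as.numeric(s$ct))
}

sample_target_matrix <- function(s) {
  as_class_matrix(s$target)
}

#' Train a model on one fold
#'
#' Runs mini-batch Adadelta on the Dice + cross-entropy loss, evaluating the
#' soft DSC on the validation patches after every epoch. Training stops after
#' `max_epochs`, or early once no strict improvement of the validation soft
#' DSC has been seen for more than `patience` epochs (`patience = 0` stops at
#' the first non-improving epoch; ties do not reset the counter). The
#' returned checkpoint holds the weights of the epoch with the highest
#' validation soft DSC.
#'
#' @param model an `mtv_model` from [build_model()].
#' @param train_data,val_data lists of patch samples; each sample is a list
#'   with 3D arrays `pet` and `ct` (values in \[0, 1\], patch-shaped) and a
#'   4D one-hot `target`.
#' @param max_epochs maximum number of epochs (study setting: 200).
#' @param patience early-stopping patience in epochs (study setting: 30).
#' @param batch_size gradient-accumulation batch size (study setting: 16).
#' @param seed integer seed for batch shuffling.
#' @param lr,rho,eps Adadelta hyperparameters (canonical defaults).
#' @param verbose print one line per epoch.
#' @return list of class `train_result` with the best `model`, the per-epoch
#'   `log` (data.frame: epoch, train_loss, val_soft_dsc), `best_epoch` and
#'   `best_val`.
#' @export
train_fold <- function(model, train_data, val_data, max_epochs = 200L,
                       patience = 30L, batch_size = 16L, seed = 1L,
                       lr = 1, rho = 0.9, eps = 1e-6, verbose = FALSE) {
  if (length(train_data) == 0 || length(val_data) == 0) {
    stop("training and validation sets must be non-empty")
  }
  cfg <- model$config
  skel <- model$params
  theta <- flatten_tree(skel)
  state <- adadelta_init(length(theta))
  dims <- cfg$patch_shape
  n_tr <- length(train_data)

  log_epoch <- integer(0); log_loss <- numeric(0); log_val <- numeric(0)
  best_val <- -Inf; best_theta <- theta; best_epoch <- 0L
  since_improve <- 0L

  withr::with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      params <- unflatten_tree(theta, skel)
      epoch_loss <- 0
      b0 <- 1L
      while (b0 <= n_tr) {
        b1 <- min(b0 + batch_size - 1L, n_tr)
        gacc <- NULL
        for (i in ord[b0:b1]) {
          s <- train_data[[i]]
          fw <- net_forward(params, cfg, sample_to_input(s), dims,
                            keep_cache = TRUE)
          lg <- dice_ce_grad(fw$probs, sample_target_matrix(s))
          if (!is.finite(lg$loss)) {
            stop(sprintf("non-finite loss at epoch %d (sample %d)", epoch, i))
          }
          epoch_loss <- epoch_loss + lg$loss
          g <- flatten_tree(net_backward(params, cfg, lg$dlogits, fw$caches))
          gacc <- if (is.null(gacc)) g else gacc + g
        }
        upd <- adadelta_step(theta, gacc / (b1 - b0 + 1L), state,
                             lr = lr, rho = rho, eps = eps)
        theta <- upd$theta; state <- upd$state
        params <- unflatten_tree(theta, skel)
        b0 <- b1 + 1L
      }
      epoch_loss <- epoch_loss / n_tr

      val <- mean(vapply(val_data, function(s) {
        pr <- net_forward(params, cfg, sample_to_input(s), dims)$probs
        soft_dsc(pr, sample_target_matrix(s))
      }, numeric(1)))

      log_epoch <- c(log_epoch, epoch)
      log_loss <- c(log_loss, epoch_loss)
      log_val <- c(log_val, val)
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f  val soft-DSC %.4f",
                        epoch, epoch_loss, val))
      }
      if (val > best_val) {
        best_val <- val; best_theta <- theta; best_epoch <- epoch
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve > patience) break
      }
    }
  })

  best <- structure(list(config = cfg,
                         params = unflatten_tree(best_theta, skel)),
                    class = "mtv_model")
  structure(list(model = best,
                 log = data.frame(epoch = log_epoch, train_loss = log_loss,
                                  val_soft_dsc = log_val),
                 best_epoch = best_epoch, best_val = best_val),
            class = "train_result")
}
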