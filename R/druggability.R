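# Per-residue ligandability labels and a small train/evaluate harness for
# an embedding-based per-residue classifier evaluated by ROC-AUC.

#' Per-residue contact label container
#' @param complex_id identifier.
#' @param labels binary vector (0/1), one entry per residue.
#' @param contact_radius radius (Angstrom) used to define contact.
#' @return A \code{residue_labels} object.
#' @export
residue_labels <- function(complex_id, labels, contact_radius) {
  ps_assert(all(labels %in% c(0L, 1L)), "bad_arg", "labels must be 0/1")
  structure(list(complex_id = complex_id, labels = as.integer(labels),
                 contact_radius = contact_radius),
            class = "residue_labels")
}

#' Label residues by ligand contact
#'
#' A residue is labelled 1 iff any of its heavy atoms lies within
#' \code{contact_radius} of any ligand heavy atom. The default 4 A is a
#' conventional heavy-atom contact cutoff (distinct from the wider
#' tessellation truncation radius).
#'
#' @param complex a [pocket_complex()].
#' @param contact_radius contact cutoff in Angstrom (default 4).
#' @return A [residue_labels()] of length \code{n_residues(complex)}.
#' @export
label_residues <- function(complex, contact_radius = 4.0) {
  d <- cross_dist(protein_coords(complex), ligand_coords(complex))
  res_min <- tapply(apply(d, 1, min), complex$atoms$seq_index, min)
  y <- as.integer(res_min[as.character(0:(n_residues(complex) - 1))] <=
                    contact_radius)
  residue_labels(complex$complex_id, y, contact_radius)
}

#' MLP configuration for the residue classifier
#'
#' @param hidden_size neurons in the hidden layer (default 8; sized for
#'   the small synthetic harnesses this package ships with).
#' @param max_epochs optimizer iteration cap (default 300).
#' @param decay L2 weight decay (default 0.1).
#' @param seed integer seed fixing the weight initialization.
#' @param class_weights \code{"inverse-frequency"} (default; contact
#'   residues are a small minority) or \code{"none"}.
#' @return An \code{mlp_config} list.
#' @export
mlp_config <- function(hidden_size = 8, max_epochs = 300, decay = 0.1,
                       seed = 1,
                       class_weights = c("inverse-frequency", "none")) {
  ps_assert(hidden_size >= 1, "bad_arg", "hidden_size must be >= 1")
  list(hidden_size = as.integer(hidden_size),
       max_epochs = as.integer(max_epochs), decay = decay,
       seed = as.integer(seed),
       class_weights = match.arg(class_weights))
}

stack_side <- function(embeddings, labels, ids) {
  miss <- setdiff(ids, intersect(names(embeddings), names(labels)))
  if (length(miss))
    ps_stop("id_mismatch", "no embeddings/labels for: %s",
            paste(head(miss, 5), collapse = ","))
  X <- do.call(rbind, lapply(ids, function(id) unclass(embeddings[[id]])))
  y <- unlist(lapply(ids, function(id) labels[[id]]$labels))
  ps_assert(nrow(X) == length(y), "id_mismatch",
            "embedding rows and labels disagree in length")
  list(X = X, y = y)
}

#' Train the per-residue ligandability classifier
#'
#' Fits a single-hidden-layer perceptron on the per-residue embedding rows
#' of the train-side complexes only. Deterministic for a fixed seed (and a
#' fixed thread count).
#'
#' @param embeddings named list of \code{residue_embedding} matrices, one
#'   per complex.
#' @param labels named list of [residue_labels()], aligned per complex.
#' @param split a \code{split_spec} over the complex ids.
#' @param cfg an [mlp_config()].
#' @return A \code{residue_mlp} with elements \code{net}, \code{cfg},
#'   \code{train_auc}, \code{split}.
#' @export
train_residue_classifier <- function(embeddings, labels, split,
                                     cfg = mlp_config()) {
  tr <- stack_side(embeddings, labels, split$train_ids)
  if (length(unique(tr$y)) < 2)
    ps_stop("degenerate_labels", "training side has a single class")
  w <- rep(1, length(tr$y))
  if (cfg$class_weights == "inverse-frequency") {
    freq <- table(tr$y) / length(tr$y)
    w <- as.numeric(1 / freq[as.character(tr$y)])
    w <- w / mean(w)
  }
  net <- with_seed(cfg$seed,
                   nnet::nnet(x = tr$X, y = tr$y, size = cfg$hidden_size,
                              weights = w, entropy = TRUE,
                              decay = cfg$decay, maxit = cfg$max_epochs,
                              MaxNWts = 100000, trace = FALSE))
  model <- structure(list(net = net, cfg = cfg, split = split,
                          dim = ncol(tr$X)),
                     class = "residue_mlp")
  model$train_auc <- rank_auc(predict(model, tr$X), tr$y)
  model
}

#' @export
predict.residue_mlp <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else unclass(newdata)
  ps_assert(ncol(X) == object$dim, "id_mismatch",
            "embedding dimension differs from the training dimension")
  as.numeric(predict(object$net, X))
}

#' @export
print.residue_mlp <- function(x, ...) {
  cat(sprintf("<residue_mlp> %d-d input, %d hidden units; train AUC %.3f (%d train complexes)\n",
              x$dim, x$cfg$hidden_size, x$train_auc,
              length(x$split$train_ids)))
  invisible(x)
}

#' Tie-aware ROC-AUC
#'
#' Rank (Mann-Whitney) formulation, equivalent to the trapezoidal area
#' under the ROC curve with tied scores handled by average ranks; invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores.
#' @param y binary labels (0/1).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    ps_stop("undefined_auc", "AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate the classifier on one side of a split
#'
#' Pools the residues of all complexes on the requested side and reports
#' the tie-aware ROC-AUC of the per-residue scores.
#'
#' @param model a \code{residue_mlp}.
#' @param embeddings,labels as in [train_residue_classifier()].
#' @param split a \code{split_spec} (defaults to the training split).
#' @param side \code{"test"} (default) or \code{"train"}.
#' @return AUC in [0, 1].
#' @export
evaluate_auc <- function(model, embeddings, labels, split = model$split,
                         side = c("test", "train")) {
  side <- match.arg(side)
  ids <- if (side == "test") split$test_ids else split$train_ids
  ps_assert(length(ids) > 0, "bad_arg", "requested side is empty")
  dat <- stack_side(embeddings, labels, ids)
  rank_auc(predict(model, dat$X), dat$y)
}
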