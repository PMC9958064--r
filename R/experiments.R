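# Paired knowledge-distillation benchmark: for each seed, train a
# teacher, a plain (non-KD) student and a distilled student on the same
# synthetic dataset from the same initial student weights, and compare
# validation accuracies.

#' Paired KD vs non-KD student comparison on synthetic data
#'
#' For every seed: generate a synthetic 6-class dataset, split 80/20,
#' train a reference-CNN teacher, train the fused student once with
#' plain cross-entropy (learning rate 0.0001) and once by distillation
#' from the teacher (temperature 2, balance 0.3, learning rate 0.001) —
#' both students start from identical initial weights — and record
#' validation accuracies. The noise level is chosen so the non-KD
#' student lands in roughly the 85-95% accuracy band, leaving the
#' distilled student measurable headroom.
#'
#' @param seeds integer seeds; one paired run per seed.
#' @param per_class samples per class.
#' @param image_size square image side in pixels.
#' @param noise synthetic pixel-noise standard deviation.
#' @param epochs training epochs for every stage.
#' @param teacher_widths stage widths of the reference-CNN teacher.
#' @return data frame with one row per seed: `seed`, `teacher_acc`,
#'   `plain_acc`, `kd_acc` (validation accuracies in `[0, 1]`) and
#'   `kd_wins` (`kd_acc >= plain_acc`).
#' @export
compare_kd <- function(seeds = 1:5, per_class = 80L, image_size = 32L,
                       noise = synth_spec()$noise, epochs = 30L,
                       teacher_widths = c(24L, 48L, 96L)) {
  rows <- lapply(seeds, function(seed) {
    sp <- synth_spec(classes = 6L, per_class = per_class,
                     image_size = image_size, noise = noise, seed = seed)
    ds <- split_dataset(synthesize_dataset(sp), 0.8, seed = seed)
    teacher_graph <- build_reference_cnn(image_size, 6L,
                                         widths = teacher_widths,
                                         seed = 1000L + seed)
    teacher <- train_classifier(teacher_graph, ds,
                                kd_config(epochs = epochs, seed = seed))
    student_graph <- build_student(image_size, 6L, seed = 2000L + seed)
    plain <- train_classifier(student_graph, ds,
                              kd_config(epochs = epochs, seed = seed))
    kd <- distill(teacher, student_graph, ds,
                  kd_config(epochs = epochs, seed = seed))
    data.frame(seed = seed,
               teacher_acc = evaluate(teacher, ds)$accuracy,
               plain_acc = evaluate(plain, ds)$accuracy,
               kd_acc = evaluate(kd, ds)$accuracy)
  })
  out <- do.call(rbind, rows)
  out$kd_wins <- out$kd_acc >= out$plain_acc
  out
}
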