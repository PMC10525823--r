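#' Task label schemes for the 14-task motor movement/imagery protocol
#'
#' The 64-channel PhysioNet motor movement/imagery protocol records 14 task
#' sessions per subject, covering six activities: eyes-open rest (t1),
#' eyes-closed rest (t2), real single-fist open/close (t3, t7, t11),
#' imagined single-fist open/close (t4, t8, t12), real both-fists/both-feet
#' (t5, t9, t13) and imagined both-fists/both-feet (t6, t10, t14).
#'
#' Three label schemes are supported:
#' \describe{
#'   \item{activity6}{the six activities a1..a6 themselves;}
#'   \item{class5}{5 classes: both rest tasks merged into one static class,
#'     the four movement/imagery activities kept apart;}
#'   \item{class3}{3 classes: rest, single-fist (real or imagined),
#'     both-fists/feet (real or imagined) --- a coarsening of class5
#'     motivated by the motor cortex activating similarly for executed and
#'     imagined movement.}
#' }
#'
#' @param name one of `"activity6"`, `"class5"`, `"class3"`.
#' @return An object of class `class_scheme`: list with `name`, `n_classes`
#'   and `mapping` (integer vector indexed by task id 1..14).
#' @examples
#' map_task_to_class(5, class_scheme("class5"))  # both-fists real -> class 4
#' @export
class_scheme <- function(name = c("activity6", "class5", "class3")) {
  name <- match.arg(name)
  activity <- c(1L, 2L, rep(c(3L, 4L, 5L, 6L), 3L))  # t1..t14
  mapping <- switch(name,
    activity6 = activity,
    class5 = c(1L, 1L, rep(c(2L, 3L, 4L, 5L), 3L)),
    class3 = c(1L, 1L, rep(c(2L, 2L, 3L, 3L), 3L)))
  structure(list(name = name, n_classes = max(mapping), mapping = mapping),
            class = "class_scheme")
}

task_id_to_int <- function(task_id) {
  if (is.character(task_id))
    task_id <- suppressWarnings(as.integer(sub("^t", "", task_id)))
  task_id <- as.integer(task_id)
  if (anyNA(task_id)) stop("unknown task id")
  task_id
}

#' Map a task id to its activity
#'
#' @param task_id integer 1..14 or string `"t1".."t14"`.
#' @return Integer activity id 1..6 (a1..a6).
#' @export
map_task_to_activity <- function(task_id) {
  map_task_to_class(task_id, class_scheme("activity6"))
}

#' Map a task id to a class under a label scheme
#'
#' @param task_id integer 1..14 or string `"t1".."t14"` (vectorized).
#' @param scheme a [class_scheme()].
#' @return Integer class id(s) under the scheme.
#' @export
map_task_to_class <- function(task_id, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  t <- task_id_to_int(task_id)
  if (any(t < 1L | t > length(scheme$mapping)))
    stop("unknown task id: ", paste(task_id[t < 1L | t > 14L], collapse = ","))
  scheme$mapping[t]
}
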