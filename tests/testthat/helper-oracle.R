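# Bridge to the independent LP/QP oracle (scipy via the system python).
# Problems are serialized to JSON, solved by inst/oracle/lp_oracle.py with
# scipy's HiGHS (LP) and trust-constr (QP) backends, and read back.

oracle_script <- function() {
  system.file("oracle", "lp_oracle.py", package = "stilflux")
}

run_oracle <- function(problems) {
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, inp, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(oracle_script(), inp, outp),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(outp)) {
    stop("LP/QP oracle run failed (python exit status ", status, ")")
  }
  jsonlite::read_json(outp, simplifyVector = FALSE)
}

matrix_rows <- function(A) {
  A <- unname(as.matrix(A))
  lapply(seq_len(nrow(A)), function(i) as.numeric(A[i, ]))
}

lp_problem <- function(obj, A, b, lb, ub, maximize = FALSE) {
  list(type = "lp", obj = unname(as.numeric(obj)), A = matrix_rows(A),
       b = unname(as.numeric(b)), lb = unname(as.numeric(lb)),
       ub = unname(as.numeric(ub)), maximize = maximize)
}

qp_problem <- function(A, b, lb, ub, vref) {
  list(type = "qp", A = matrix_rows(A), b = unname(as.numeric(b)),
       lb = unname(as.numeric(lb)), ub = unname(as.numeric(ub)),
       vref = unname(as.numeric(vref)))
}

fba_lp_problem <- function(model, objective = NULL, maximize = TRUE) {
  ob <- stilflux:::fba_objective_vector(model, objective)
  S <- as.matrix(stoichiometric_matrix(model))
  lp_problem(ob$vec, S, rep(0, nrow(S)), model$reactions$lb,
             model$reactions$ub, maximize = maximize)
}

oracle_objective <- function(res) {
  vapply(res, function(r) {
    if (identical(r$status, "optimal")) as.numeric(r$objective) else NA_real_
  }, numeric(1))
}
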