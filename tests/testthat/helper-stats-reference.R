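# Cross-implementation reference for the statistical tests: the same
# hypothesis tests computed by SciPy / statsmodels through the system
# `python`. Each element of `cases` is a list with a `kind` and its data;
# one batched subprocess call returns all reference p-values.

reference_pvalues_script <- '
import json, sys
from scipy import stats
from statsmodels.stats.contingency_tables import mcnemar

with open(sys.argv[1]) as fh:
    cases = json.load(fh)
out = {}
for key, d in cases.items():
    kind = d["kind"]
    if kind == "t":
        p = stats.ttest_ind(d["a"], d["b"], equal_var=True).pvalue
    elif kind == "t_paired":
        p = stats.ttest_rel(d["a"], d["b"]).pvalue
    elif kind == "ranksum":
        p = stats.mannwhitneyu(d["a"], d["b"], alternative="two-sided",
                               method="exact").pvalue
    elif kind == "signedrank":
        p = stats.wilcoxon(d["a"], d["b"], alternative="two-sided",
                           method="exact").pvalue
    elif kind == "chisq":
        p = stats.chi2_contingency(d["table"], correction=False)[1]
    elif kind == "mcnemar_exact":
        p = mcnemar(d["table"], exact=True).pvalue
    elif kind == "mcnemar_chisq":
        p = mcnemar(d["table"], exact=False, correction=False).pvalue
    elif kind == "ks":
        p = stats.kstest(d["x"], "norm", method="asymp").pvalue
    else:
        raise ValueError(kind)
    out[key] = float(p)
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'

reference_pvalues <- function(cases) {
  stopifnot(length(names(cases)) == length(cases))
  in_path <- tempfile(fileext = ".json")
  out_path <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  writeLines(reference_pvalues_script, script)
  jsonlite::write_json(cases, in_path, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, in_path, out_path),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_path)) {
    stop("reference implementation failed: ",
         paste(status, collapse = "\n"))
  }
  unlist(jsonlite::read_json(out_path))
}
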