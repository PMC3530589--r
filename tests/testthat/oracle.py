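# Independent constraint-based oracle for the R test suite.
# Reads a JSON list of requests ({"path": model.json, "op": "fba"|"fva",
# "objective": optional reaction id, "reaction": for fva, "fraction": ...}),
# evaluates each with cobrapy/GLPK, writes a JSON list of results.
import json
import sys

import cobra.io
from cobra.flux_analysis import flux_variability_analysis


def main(inp, outp):
    requests = json.load(open(inp))
    results = []
    for req in requests:
        path = req["path"]
        if path.endswith((".xml", ".sbml")):
            model = cobra.io.read_sbml_model(path)
        else:
            model = cobra.io.load_json_model(path)
        if req.get("objective"):
            model.objective = req["objective"]
        op = req.get("op", "fba")
        if op == "fba":
            val = model.slim_optimize(error_value=None)
            results.append(
                {
                    "objective": val,
                    "n_metabolites": len(model.metabolites),
                    "n_reactions": len(model.reactions),
                    "n_genes": len(model.genes),
                }
            )
        elif op == "fva":
            res = flux_variability_analysis(
                model,
                reaction_list=[req["reaction"]],
                fraction_of_optimum=req.get("fraction", 1.0),
            )
            results.append(
                {"min": float(res.minimum.iloc[0]), "max": float(res.maximum.iloc[0])}
            )
        else:
            raise ValueError("unknown op: %s" % op)
    json.dump(results, open(outp, "w"))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
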