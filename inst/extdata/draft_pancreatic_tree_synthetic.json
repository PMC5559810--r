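{
  "schema_version": "1.0",
  "comment": "Synthetic transcription of a first-draft treatment algorithm for metastatic pancreatic cancer, deliberately imperfect: undeclared double recommendation for fit patients; overlapping BSC/Gem branches and a coverage gap for unfit patients.",
  "participant": {
    "id": "draft-center",
    "finalisation_date": "2017-01-15"
  },
  "criteria": [
    {
      "name": "age",
      "levels": ["<75", ">=75"],
      "description": "patient age in years",
      "kind": "categorical"
    },
    {
      "name": "fitness",
      "levels": ["fit", "unfit"],
      "description": "overall patient fitness",
      "kind": "categorical"
    }
  ],
  "root": {
    "criterion": "fitness",
    "branches": [
      {
        "levels": ["fit"],
        "node": {
          "recommendations": ["FOLFIRINOX", "Gem"],
          "multiplicity": "single"
        }
      },
      {
        "levels": ["unfit"],
        "node": {
          "criterion": "age",
          "branches": [
            {
              "levels": [">=75"],
              "node": { "recommendations": ["BSC"], "multiplicity": "single" }
            },
            {
              "levels": [">=75"],
              "node": { "recommendations": ["Gem"], "multiplicity": "single" }
            }
          ]
        }
      }
    ]
  }
}
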