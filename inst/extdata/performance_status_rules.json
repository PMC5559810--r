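{
  "schema_version": "1.0",
  "target_criteria": [
    {
      "name": "fitness",
      "levels": [
        "fit",
        "unfit"
      ],
      "description": "harmonized patient fitness",
      "kind": "derived-from-cutoff",
      "source": {
        "scale": "multiple",
        "cutoff": null
      }
    }
  ],
  "rules": [
    {
      "participant": "A",
      "source": "KPS",
      "target": "fitness",
      "map": {
        ">=50": "fit",
        "<50": "unfit"
      },
      "source_scale": "KPS",
      "cutoff": 50
    },
    {
      "participant": "B",
      "source": "KPS",
      "target": "fitness",
      "map": {
        ">=60": "fit",
        "<60": "unfit"
      },
      "source_scale": "KPS",
      "cutoff": 60
    },
    {
      "participant": "C",
      "source": "KPS",
      "target": "fitness",
      "map": {
        ">=70": "fit",
        "<70": "unfit"
      },
      "source_scale": "KPS",
      "cutoff": 70
    },
    {
      "participant": "D",
      "source": "KPS",
      "target": "fitness",
      "map": {
        ">=90": "fit",
        "<90": "unfit"
      },
      "source_scale": "KPS",
      "cutoff": 90
    },
    {
      "participant": "E",
      "source": "ECOG",
      "target": "fitness",
      "map": {
        "<=1": "fit",
        ">1": "unfit"
      },
      "source_scale": "ECOG",
      "cutoff": 1
    },
    {
      "participant": "F",
      "source": "global_impression",
      "target": "fitness",
      "map": {
        "good": "fit",
        "bad": "unfit"
      },
      "note": "no specific scale used by this center; good/bad mapped 1:1 to fit/unfit by moderation"
    }
  ]
}
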