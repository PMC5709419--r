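[
  {
    "name": "Zur",
    "assembly": "dimer",
    "abundance": {"count": 21, "sd": 7},
    "dna_targets": 4,
    "mode": "co_repressor",
    "apo_dna_kd": {"kd_M": 2.7e-5, "bound": "lower", "sd_M": 4e-6},
    "metals": {
      "Co": {
        "metal_kd": {"kd_M": 1.5e-8, "bound": "exact", "sd_M": 6e-9},
        "holo_dna_kd": {"kd_M": 3.1e-8, "bound": "exact", "sd_M": 3e-9}
      },
      "Zn": {
        "metal_kd": {"kd_M": 6.4e-13, "bound": "exact", "sd_M": 4e-14},
        "holo_dna_kd": {"kd_M": 4.1e-8, "bound": "exact", "sd_M": 1e-8},
        "note": "two tightest exchangeable Zn(II) sites filled (Zn2 state)"
      },
      "Zn4": {
        "metal_kd": null,
        "holo_dna_kd": {"kd_M": 5.4e-8, "bound": "exact", "sd_M": 1.8e-8},
        "note": "all four exchangeable Zn(II) sites filled; no combined metal Kd"
      }
    }
  },
  {
    "name": "ZntR",
    "assembly": "dimer",
    "abundance": {"count": 34, "sd": 15},
    "dna_targets": 1,
    "mode": "activator",
    "apo_dna_kd": {"kd_M": 1.1e-6, "bound": "exact", "sd_M": 3e-7},
    "metals": {
      "Co": {
        "metal_kd": {"kd_M": 9.5e-8, "bound": "exact", "sd_M": 1e-8},
        "holo_dna_kd": {"kd_M": 3.4e-7, "bound": "exact", "sd_M": 1e-7}
      },
      "Zn": {
        "metal_kd": {"kd_M": 3.2e-12, "bound": "exact", "sd_M": 7e-13},
        "holo_dna_kd": {"kd_M": 6.5e-7, "bound": "exact", "sd_M": 3.3e-7}
      }
    }
  },
  {
    "name": "RcnR",
    "assembly": "tetramer",
    "abundance": {"count": 22, "sd": 2},
    "dna_targets": 1,
    "mode": "de_repressor",
    "apo_dna_kd": {"kd_M": 1.5e-7, "bound": "exact", "sd_M": 8e-8},
    "metals": {
      "Co": {
        "metal_kd": {"kd_M": 5.1e-10, "bound": "exact", "sd_M": 9e-11},
        "holo_dna_kd": {"kd_M": 1.5e-5, "bound": "lower", "sd_M": 2e-6}
      },
      "Zn": {
        "metal_kd": {"kd_M": 9.4e-12, "bound": "exact", "sd_M": 1e-12},
        "holo_dna_kd": {"kd_M": 1.3e-5, "bound": "lower", "sd_M": 2e-6}
      }
    }
  },
  {
    "name": "FrmR_E64H",
    "assembly": "tetramer",
    "abundance": {"count": 149, "sd": 4},
    "dna_targets": 15,
    "mode": "de_repressor",
    "apo_dna_kd": {"kd_M": 4.3e-7, "bound": "exact", "sd_M": 4e-8},
    "metals": {
      "Co": {
        "metal_kd": {"kd_M": 2.6e-7, "bound": "exact", "sd_M": 4e-8},
        "holo_dna_kd": {"kd_M": 2.3e-6, "bound": "exact", "sd_M": 3e-7}
      },
      "Zn": {
        "metal_kd": {"kd_M": 2.3e-11, "bound": "exact", "sd_M": 3e-12},
        "holo_dna_kd": {"kd_M": 3.5e-6, "bound": "exact", "sd_M": 7e-7}
      }
    }
  },
  {
    "name": "FrmR",
    "assembly": "tetramer",
    "abundance": {"count": 135, "sd": 17},
    "dna_targets": 15,
    "mode": "de_repressor",
    "apo_dna_kd": {"kd_M": 9.9e-8, "bound": "exact", "sd_M": 3e-9},
    "metals": {
      "Co": {
        "metal_kd": {"kd_M": 7.6e-6, "bound": "exact", "sd_M": 4e-7},
        "holo_dna_kd": null
      },
      "Zn": {
        "metal_kd": {"kd_M": 1.7e-10, "bound": "exact", "sd_M": 7e-11},
        "holo_dna_kd": {"kd_M": 3.1e-6, "bound": "exact", "sd_M": 4e-7}
      }
    }
  }
]
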