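{
  "primary": [
    {"module": "head_and_brain", "keywords": ["concussion", "craniocerebral injury", "cerebral contusion"], "weight": 5},
    {"module": "neck", "keywords": ["cervical spine injury", "cervical spine fracture"], "weight": 1},
    {"module": "thorax", "keywords": ["rib fracture", "lung contusion", "hemopneumothorax"], "weight": 2},
    {"module": "belly", "keywords": ["abdominal hemorrhage", "splenic rupture", "liver laceration"], "weight": 3},
    {"module": "fracture_limb_pelvis", "keywords": ["fracture", "fracture reduction"], "weight": 1},
    {"module": "spine_spinal_cord", "keywords": ["spinal fracture", "spinal cord injury"], "weight": 3},
    {"module": "multiple_injuries", "keywords": ["multiple trauma", "multi-site injury"], "weight": 5}
  ],
  "other": [
    {"module": "hemorrhagic", "keywords": ["hematoma", "internal bleeding"], "weight": 5},
    {"module": "organ_injury", "keywords": ["liver injury", "kidney injury"], "weight": 1},
    {"module": "cardiovascular", "keywords": ["heart injury", "pericardial effusion"], "weight": 5},
    {"module": "soft_tissue", "keywords": ["muscle injury", "ligament tear"], "weight": 1},
    {"module": "fracture_other", "keywords": ["open fracture", "closed fracture"], "weight": 1},
    {"module": "vertebra", "keywords": ["spinal cord injury", "nerve injury"], "weight": 1},
    {"module": "underlying_disease", "keywords": ["diabetes", "high blood pressure", "coronary atherosclerosis"], "weight": 4}
  ]
}
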