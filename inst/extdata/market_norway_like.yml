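# Default synthetic market: group sizes and additive prevalences loosely
# shaped on the Norwegian packaged-food market (scenery for validation, not
# reference values). Shares are normalized at load time.
style_probs: {enumber: 0.45, name: 0.30, misspelled: 0.15, subclass: 0.10}
defect_rates:
  non_food: 0.020
  no_ingredients: 0.030
  nutrient_gt_100: 0.002
  sugar_gt_carb: 0.003
  satfat_gt_fat: 0.003
  no_energy: 0.004
  energy_gt_4200: 0.001
  bad_kj_kcal_ratio: 0.002
  duplicate: 0.030
nutrition_profiles:
  dessert:  {fat: [2.2, 0.5], carb: [3.2, 0.4], protein: [1.3, 0.4], salt: [-1.6, 0.6], sugar_frac: [5, 2], satfat_frac: [4, 2]}
  bakery:   {fat: [2.4, 0.5], carb: [3.6, 0.3], protein: [2.0, 0.3], salt: [0.0, 0.4], sugar_frac: [2, 4], satfat_frac: [2, 3]}
  savory:   {fat: [2.5, 0.6], carb: [1.6, 0.8], protein: [2.8, 0.3], salt: [0.5, 0.5], sugar_frac: [1, 6], satfat_frac: [2, 3]}
  fatty:    {fat: [3.9, 0.4], carb: [1.0, 0.8], protein: [0.9, 0.6], salt: [0.2, 0.6], sugar_frac: [1, 6], satfat_frac: [2, 2]}
  lean:     {fat: [0.9, 0.8], carb: [2.4, 0.7], protein: [1.6, 0.6], salt: [-1.2, 0.8], sugar_frac: [2, 3], satfat_frac: [1, 4]}
  beverage: {fat: [-1.5, 0.8], carb: [2.1, 0.7], protein: [-0.7, 0.8], salt: [-3.0, 0.8], sugar_frac: [6, 2], satfat_frac: [1, 6]}
  infant:   {fat: [1.1, 0.5], carb: [2.2, 0.4], protein: [1.2, 0.4], salt: [-2.5, 0.6], sugar_frac: [2, 3], satfat_frac: [1, 4]}
groups:
  - name: "Meat & Poultry"
    share: 0.22
    nutrition: savory
    archetypes:
      - weight: 0.72
        probs: {}
      - weight: 0.28
        probs: {E450: 0.85, E451: 0.78, E452: 0.30, E407: 0.25, E412: 0.15, E415: 0.12, E425: 0.06, E460: 0.05}
  - name: "Bakery, Cakes & Pastries"
    share: 0.12
    nutrition: bakery
    archetypes:
      - weight: 0.34
        probs: {}
      - weight: 0.40
        probs: {E471: 0.80, E472: 0.70, E415: 0.30, E422: 0.35, E450: 0.30, E420: 0.15, E481: 0.10, E466: 0.10}
      - weight: 0.26
        probs: {E471: 0.50, E472: 0.40, E412: 0.30, E466: 0.25, E481: 0.08, E482: 0.05}
  - name: "Eggs & Dairy Products"
    share: 0.10
    nutrition: lean
    archetypes:
      - weight: 0.70
        probs: {}
      - weight: 0.30
        probs: {E407: 0.40, E410: 0.35, E412: 0.30, E415: 0.20, E440: 0.15, E471: 0.20, E406: 0.08, E418: 0.05, E460: 0.06}
  - name: "Beverages"
    share: 0.09
    nutrition: beverage
    archetypes:
      - weight: 0.70
        probs: {}
      - weight: 0.30
        probs: {E440: 0.30, E407: 0.25, E412: 0.20, E415: 0.20, E445: 0.10, E414: 0.15, E418: 0.05}
  - name: "Snacks, Chocolate & Sweets"
    share: 0.08
    nutrition: dessert
    archetypes:
      - weight: 0.65
        probs: {}
      - weight: 0.35
        probs: {E471: 0.50, E422: 0.30, E420: 0.25, E414: 0.20, E472: 0.25, E421: 0.08, E413: 0.05, E473: 0.05}
  - name: "Premade Food & Dinner Kits"
    share: 0.07
    nutrition: savory
    archetypes:
      - weight: 0.60
        probs: {}
      - weight: 0.40
        probs: {E412: 0.40, E415: 0.35, E450: 0.30, E451: 0.28, E471: 0.30, E466: 0.12, E461: 0.05}
  - name: "Sauces, Dressings & Other Dinner Condiments"
    share: 0.06
    nutrition: savory
    archetypes:
      - weight: 0.50
        probs: {}
      - weight: 0.50
        probs: {E412: 0.60, E415: 0.65, E440: 0.20, E466: 0.20, E471: 0.20, E405: 0.10, E416: 0.04, E417: 0.05}
  - name: "Fish & Shellfish"
    share: 0.05
    nutrition: savory
    archetypes:
      - weight: 0.65
        probs: {}
      - weight: 0.35
        probs: {E450: 0.50, E451: 0.45, E407: 0.20, E412: 0.25, E415: 0.22, E452: 0.15, E401: 0.08}
  - name: "Grains, Baking Mixes & Cereals"
    share: 0.05
    nutrition: bakery
    archetypes:
      - weight: 0.75
        probs: {}
      - weight: 0.25
        probs: {E471: 0.40, E472: 0.30, E466: 0.15, E412: 0.20, E422: 0.10}
  - name: "Fruit, Vegetables & Legumes"
    share: 0.045
    nutrition: lean
    archetypes:
      - weight: 0.90
        probs: {}
      - weight: 0.10
        probs: {E440: 0.30, E407: 0.20, E401: 0.10}
  - name: "Processed Fruits & Vegetables"
    share: 0.04
    nutrition: lean
    archetypes:
      - weight: 0.60
        probs: {}
      - weight: 0.40
        probs: {E440: 0.50, E407: 0.15, E412: 0.20, E466: 0.15, E400: 0.06, E402: 0.04}
  - name: "Fats, Margarine & Spreads"
    share: 0.035
    nutrition: fatty
    archetypes:
      - weight: 0.45
        probs: {}
      - weight: 0.55
        probs: {E471: 0.70, E412: 0.45, E415: 0.40, E476: 0.20, E475: 0.12, E474: 0.05, E477: 0.08}
  - name: "Desserts & Ice Creams"
    share: 0.03
    nutrition: dessert
    archetypes:
      - weight: 0.16
        probs: {}
      - weight: 0.50
        probs: {E471: 0.85, E412: 0.75, E415: 0.50, E407: 0.45, E410: 0.40, E440: 0.20, E433: 0.10, E491: 0.08, E477: 0.06}
      - weight: 0.34
        probs: {E440: 0.70, E401: 0.50, E450: 0.45, E452: 0.30, E471: 0.30, E460: 0.15, E466: 0.15, E470: 0.08}
  - name: "Baking Condiments"
    share: 0.03
    nutrition: bakery
    archetypes:
      - weight: 0.60
        probs: {}
      - weight: 0.40
        probs: {E415: 0.30, E412: 0.25, E466: 0.20, E450: 0.35, E471: 0.20, E459: 0.04, E464: 0.05}
  - name: "Infant Food"
    share: 0.007
    nutrition: infant
    archetypes:
      - weight: 0.97
        probs: {}
      - weight: 0.03
        probs: {E440: 0.80}
  - name: "Others"
    share: 0.028
    nutrition: savory
    archetypes:
      - weight: 0.70
        probs: {}
      - weight: 0.30
        probs: {E412: 0.30, E415: 0.25, E471: 0.25, E450: 0.20, E431: 0.03, E432: 0.03, E434: 0.02, E435: 0.03, E436: 0.02, E442: 0.04, E456: 0.02, E463: 0.03, E465: 0.02, E482: 0.03}
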