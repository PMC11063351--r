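category,dish_name,method,fat,fat_flag,protein,protein_flag,sodium,sodium_flag,carbohydrate,carbohydrate_flag
Rice,Rice,Boiling,0.55,FALSE,1.08,FALSE,0.36,TRUE,0.63,FALSE
Rice,Steamed rice,Steaming,0.62,FALSE,0.86,FALSE,0.90,FALSE,0.66,FALSE
Rice,Fried rice,Stir-frying,1.68,FALSE,2.17,TRUE,0.47,TRUE,1.44,FALSE
Noodles,Soup noodles,Boiling,0.04,TRUE,0.95,FALSE,7.24,TRUE,0.77,FALSE
Noodles,Fried noodles,Stir-frying,3.50,TRUE,3.24,TRUE,0.47,TRUE,0.60,FALSE
Chicken breast,Braised chicken breast,Stewing (with soy sauce),0.93,FALSE,0.92,FALSE,1.39,FALSE,0.07,TRUE
Chicken breast,Deep-fried chicken breast (breaded with flour),Deep frying,4.95,TRUE,0.84,FALSE,2.24,TRUE,0.09,TRUE
Chicken breast,Fried Chicken,Stir-frying,4.06,TRUE,0.97,FALSE,2.24,TRUE,0.07,TRUE
Chicken Legs,Braised Chicken Legs,Stewing (with soy sauce),0.67,FALSE,0.58,FALSE,0.49,TRUE,0.00,TRUE
Chicken Legs,Steamed chicken thighs (cut into pieces and steamed),Steaming,0.79,FALSE,0.86,FALSE,0.40,TRUE,0.00,TRUE
Chicken Legs,Fried chicken thighs (coated with flour),Deep frying,1.48,FALSE,0.83,FALSE,1.12,FALSE,0.09,TRUE
Chicken Legs,Grilled Chicken Legs,Roasting,1.15,FALSE,1.07,FALSE,1.19,FALSE,0.33,TRUE
Pork belly,Braised Pork,Stewing (with soy sauce),0.76,FALSE,0.76,FALSE,1.11,FALSE,0.11,TRUE
Pork belly,Steamed pork practice,Steaming,1.17,FALSE,0.82,FALSE,1.03,FALSE,0.03,TRUE
Pork belly,Stir-fried Shredded Pork with Green Pepper,Stir-frying,0.86,FALSE,0.65,FALSE,0.23,TRUE,0.31,TRUE
Pork belly,Grilled Pork,Roasting,0.85,FALSE,0.75,FALSE,0.39,TRUE,0.25,TRUE
Pork Legs,Steamed pork with vermicelli,Steaming,1.21,FALSE,0.85,FALSE,0.21,TRUE,0.16,TRUE
Pork Legs,Small crispy pork (coated with flour and fried),Deep frying,2.85,TRUE,1.10,FALSE,1.06,FALSE,0.57,FALSE
Pork Legs,Pasteurized pork,Stir-frying,0.68,FALSE,2.03,TRUE,0.69,FALSE,1.06,FALSE
Pork Legs,Braised Pork,Stewing (with soy sauce),0.88,FALSE,0.69,FALSE,0.22,TRUE,0.58,FALSE
Brisket,Braised Beef Brisket,Stewing (with soy sauce),0.99,FALSE,0.49,TRUE,0.18,TRUE,0.09,TRUE
Brisket,Grilled Beef Brisket,Roasting,1.94,FALSE,0.94,FALSE,0.34,TRUE,0.10,TRUE
Brisket,Stir Fried Beef Brisket,Stir-frying,1.44,FALSE,1.01,FALSE,0.32,TRUE,0.06,TRUE
Beef Tendon,Stir Fried Beef,Stir-frying,0.86,FALSE,0.94,FALSE,0.20,TRUE,0.04,TRUE
Beef Tendon,Grilled Beef Tendon with Sauce,Roasting,2.58,TRUE,2.61,TRUE,0.73,FALSE,0.45,TRUE
Beef Tendon,Braised Beef Tendon,Stewing (with soy sauce),0.48,TRUE,0.62,FALSE,0.72,FALSE,0.15,TRUE
Leg of lamb,(Cumin) Lamb,Stir-frying,0.45,TRUE,0.76,FALSE,0.30,TRUE,0.07,TRUE
Leg of lamb,Roast Lamb,Roasting,0.58,FALSE,0.67,FALSE,0.34,TRUE,0.06,TRUE
Leg of lamb,Braised Lamb Shank,Stewing (with soy sauce),0.64,FALSE,0.86,FALSE,0.34,TRUE,0.06,TRUE
Grass carp,Braised Grass Carp,Stewing (with soy sauce),0.64,FALSE,0.30,TRUE,0.25,TRUE,0.13,TRUE
Grass carp,Fried Grass Carp,Deep frying,1.14,FALSE,0.35,TRUE,0.48,TRUE,0.32,TRUE
Grass carp,Steamed Grass Carp,Steaming,1.13,FALSE,0.70,FALSE,1.04,FALSE,0.03,TRUE
Grass carp,Grilled Grass Carp,Roasting,4.03,TRUE,1.84,FALSE,1.79,FALSE,0.01,TRUE
Hairtail,Steamed hairtail,Steaming,2.18,TRUE,1.78,FALSE,3.02,TRUE,0.52,FALSE
Hairtail,Braised hairtail,Stewing (with soy sauce),0.94,FALSE,0.27,TRUE,0.19,TRUE,0.10,TRUE
Hairtail,Deep Fried hairtail Pieces,Deep frying,0.59,FALSE,0.42,TRUE,0.45,TRUE,0.51,FALSE
Shrimp,Prawns in oil,deep frying,1.59,FALSE,0.75,FALSE,0.94,FALSE,0.60,FALSE
Shrimp,Steamed shrimp,Steaming,0.90,FALSE,1.68,FALSE,1.03,FALSE,0.21,TRUE
Shrimp,Boiled Shrimp,Quick-boiling,0.94,FALSE,2.00,TRUE,4.46,TRUE,0.19,TRUE
Eggs,Scrambled eggs with green peppers,Stir-frying,0.44,TRUE,0.60,FALSE,0.50,TRUE,0.67,FALSE
Eggs,Hard-boiled eggs,Stewing (with soy sauce),0.58,FALSE,1.06,FALSE,1.17,FALSE,0.39,TRUE
Eggs,Fried Eggs,Stir-frying,1.33,FALSE,0.70,FALSE,0.43,TRUE,0.07,TRUE
Pakchoi cabbage,Stir Fried Pakchoi cabbage,Stir-frying,1.23,FALSE,0.56,FALSE,0.92,FALSE,0.12,TRUE
Pakchoi cabbage,Quick-boiled Pakchoi cabbage,Quick-boiling,0.00,TRUE,0.81,FALSE,1.50,FALSE,0.11,TRUE
Potatoes,Hot and Sour Shredded Potatoes,Stir-frying,2.97,TRUE,4.58,TRUE,1.98,FALSE,1.87,FALSE
Potatoes,Baked Potatoes,Roasting,0.13,TRUE,0.66,FALSE,0.57,FALSE,0.51,FALSE
Potatoes,French fries (chips),Deep frying,2.24,TRUE,0.53,FALSE,0.29,TRUE,0.37,TRUE
Potatoes,Boiled potatoes,Stewing (with soy sauce),1.11,FALSE,0.36,TRUE,0.07,TRUE,0.21,TRUE
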