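category,subclass,dish_name,method,ratio
Rice,rice,Steamed Rice,Steaming,0.49
Rice,rice,Fried Rice,Stir-frying,0.48
Noodles,noodles,Noodles in Soup,Boiling,0.84
Noodles,noodles,Fried Noodles,Stir-frying,0.78
Chicken breast,chicken_breast,Braised Chicken Breast,Stewing (with soy sauce),1.05
Chicken breast,chicken_breast,Deep-fried chicken breast (covered with flour),Deep-frying,1.25
Chicken breast,chicken_breast,Fried Chicken,Stir-frying,0.97
Chicken Legs,chicken_leg,Braised Chicken Thighs,Stewing (with soy sauce),1.22
Chicken Legs,chicken_leg,Steamed chicken thighs (cut into pieces and steamed),Steaming,0.95
Chicken Legs,chicken_leg,Fried Chicken Legs (Flour Coated),Deep-frying,1.08
Chicken Legs,chicken_leg,Grilled chicken thighs,Roasting,1.43
Pork Five-flower,pork_belly,Braised Pork,Stewing (with soy sauce),1.28
Pork Five-flower,pork_belly,Stir-fried Shredded Pork with Green Pepper,Stir-frying,1.05
Pork shank,pork_leg,Steamed Pork in Vermicelli,Steaming,0.65
Pork shank,pork_leg,Small crispy pork (breaded and fried),Deep-frying,1.25
Pork shank,pork_leg,Back-pot meat,Stir-frying,1.12
Pork shank,pork_leg,Braised Pork,Stewing (with soy sauce),1.26
Beef Brisket,beef_brisket,Braised Beef Brisket,Stewing (with soy sauce),1.35
Beef Brisket,beef_brisket,Roast Beef Brisket,Roasting,1.07
Beef Brisket,beef_brisket,Stir Fried Beef Brisket,Stir-frying,1.16
Beef Tendon,beef_tendon,Stir Fried Beef,Stir-frying,1.06
Beef Tendon,beef_tendon,Roast Beef Tendon with Sauce,Roasting,1.10
Beef Tendon,beef_tendon,Braised Beef Tendon,Stewing (with soy sauce),1.34
Leg of lamb,lamb_leg,(Cumin) Lamb,Stir-frying,1.21
Leg of lamb,lamb_leg,Roast Lamb,Roasting,1.24
Leg of lamb,lamb_leg,Braised Lamb Shank,Stewing (with soy sauce),1.47
Grass carp,grass_carp,Braised Grass Carp,Stewing (with soy sauce),0.96
Grass carp,grass_carp,Deep Fried Grass Carp,Deep-frying,1.11
Grass carp,grass_carp,Steamed Grass Carp,Steaming,1.01
Grass carp,grass_carp,Grilled Grass Carp,Roasting,1.11
Hairtail,hairtail,Steamed hairtail,Steaming,1.09
Hairtail,hairtail,Braised hairtail,Stewing (with soy sauce),0.91
Hairtail,hairtail,Deep Fried hairtail Pieces,Deep-frying,1.17
Shrimp,shrimp,Stewed Prawns,Deep-frying,0.82
Shrimp,shrimp,Steamed Prawns,Steaming,1.27
Shrimp,shrimp,Boiled Prawns,Stewing (with soy sauce),1.13
Egg,egg,Scrambled Eggs with Green Peppers,Stir-frying,0.92
Egg,egg,Boiled Eggs,Stewing (with soy sauce),1.01
Egg,egg,Fried Eggs,Stir-frying,1.14
Pakchoi cabbage,pakchoi,Stir Fried pakchoi cabbage,Stir-frying,1.05
Pakchoi cabbage,pakchoi,Quick-boiled Pakchoi cabbage,Quick-boiling,1.00
Potatoes,potato,Spicy and sour shredded potatoes,Stir-frying,1.12
Potatoes,potato,Fried French fries (slices),Deep-frying,1.53
Potatoes,potato,Boiled potatoes,Stewing (with soy sauce),1.05
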