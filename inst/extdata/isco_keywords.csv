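keyword,occupation_group
engineer,professionals
software engineer,professionals
teacher,professionals
professor,professionals
lawyer,professionals
accountant,professionals
architect,professionals
scientist,professionals
journalist,professionals
chartered accountant,professionals
analyst,professionals
consultant,professionals
designer,professionals
manager,managers
director,managers
executive,managers
business owner,managers
proprietor,managers
salesperson,service_and_sales
sales,service_and_sales
shopkeeper,service_and_sales
waiter,service_and_sales
cashier,service_and_sales
cook,service_and_sales
hairdresser,service_and_sales
security guard,service_and_sales
police,service_and_sales
driver,elementary
labourer,elementary
laborer,elementary
cleaner,elementary
farm worker,elementary
helper,elementary
domestic worker,elementary
construction worker,elementary
sweeper,elementary
clerk,clerical
secretary,clerical
typist,clerical
office assistant,clerical
receptionist,clerical
data entry operator,clerical
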