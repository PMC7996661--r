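surface	normalized_label	kind	is_status
accountancy	accountancy	description	FALSE
accountant	accountant	title	FALSE
actor	actor	title	FALSE
actress	actress	title	FALSE
administration	administration	description	FALSE
advertising	advertising	description	FALSE
architect	architect	title	FALSE
artist	artist	title	FALSE
author	author	title	FALSE
baker	baker	title	FALSE
banker	banker	title	FALSE
barber	barber	title	FALSE
barrister	barrister	title	FALSE
bartender	bartender	title	FALSE
bookmaker	bookmaker	title	FALSE
builder	builder	title	FALSE
bus driver	bus driver	title	FALSE
busker	busker	title	FALSE
butcher	butcher	title	FALSE
call handler	call handler	title	FALSE
care coordinator	care coordinator	title	FALSE
carer	carer	title	TRUE
caretaker	caretaker	title	FALSE
carpenter	carpenter	title	FALSE
cashier	cashier	title	FALSE
catering	catering	description	FALSE
chauffeur	chauffeur	title	FALSE
chef	chef	title	FALSE
childcare	childcare	description	FALSE
childminder	childminder	title	FALSE
cleaner	cleaner	title	FALSE
cleaning	cleaning	description	FALSE
clinical psychologist	psychologist	title	FALSE
community psychiatric nurse	nurse	title	FALSE
construction	construction	description	FALSE
consultant psychiatrist	psychiatrist	title	FALSE
counsellor	counsellor	title	FALSE
courier	courier	title	FALSE
croupier	croupier	title	FALSE
customer adviser	customer adviser	title	FALSE
dancer	dancer	title	FALSE
decorator	decorator	title	FALSE
delivery driver	delivery driver	title	FALSE
dentist	dentist	title	FALSE
dinner lady	dinner lady	title	FALSE
doctor	doctor	title	FALSE
dog walker	dog walker	title	FALSE
drug dealer	drug dealer	title	FALSE
dry cleaner	dry cleaner	title	FALSE
economist	economist	title	FALSE
editor	editor	title	FALSE
electrician	electrician	title	FALSE
engineer	engineer	title	FALSE
engineering	engineering	description	FALSE
estate agent	estate agent	title	FALSE
factory worker	factory worker	title	FALSE
farmer	farmer	title	FALSE
farming	farming	description	FALSE
finance	finance	description	FALSE
financial analyst	financial analyst	title	FALSE
firefighter	firefighter	title	FALSE
fisherman	fisherman	title	FALSE
fitness instructor	fitness instructor	title	FALSE
flight attendant	flight attendant	title	FALSE
florist	florist	title	FALSE
fortune teller	fortune teller	title	FALSE
gardener	gardener	title	FALSE
general practitioner	doctor	title	FALSE
gp	doctor	title	FALSE
graphic designer	graphic designer	title	FALSE
hairdresser	hairdresser	title	FALSE
hospitality	hospitality	description	FALSE
insurance	insurance	description	FALSE
jeweller	jeweller	title	FALSE
journalism	journalism	description	FALSE
journalist	journalist	title	FALSE
junior doctor	doctor	title	FALSE
kitchen porter	kitchen porter	title	FALSE
lab technician	lab technician	title	FALSE
labourer	labourer	title	FALSE
launderette attendant	launderette attendant	title	FALSE
lawyer	lawyer	title	FALSE
lecturer	lecturer	title	FALSE
librarian	librarian	title	FALSE
lifeguard	lifeguard	title	FALSE
logistics	logistics	description	FALSE
lorry driver	lorry driver	title	FALSE
manufacturing	manufacturing	description	FALSE
market trader	market trader	title	FALSE
marketing	marketing	description	FALSE
mechanic	mechanic	title	FALSE
mental health nurse	nurse	title	FALSE
musician	musician	title	FALSE
nurse	nurse	title	FALSE
nursery assistant	nursery assistant	title	FALSE
occupational therapist	therapist	title	FALSE
optician	optician	title	FALSE
painter	painter	title	FALSE
paralegal	paralegal	title	FALSE
paramedic	paramedic	title	FALSE
personal assistant	personal assistant	title	FALSE
personal trainer	personal trainer	title	FALSE
pharmacist	pharmacist	title	FALSE
photographer	photographer	title	FALSE
pilot	pilot	title	FALSE
plumber	plumber	title	FALSE
plumbing	plumbing	description	FALSE
police officer	police officer	title	FALSE
postman	postman	title	FALSE
professor	professor	title	FALSE
programmer	programmer	title	FALSE
psychiatrist	psychiatrist	title	FALSE
psychologist	psychologist	title	FALSE
psychotherapist	therapist	title	FALSE
receptionist	receptionist	title	FALSE
referee	referee	title	FALSE
removal man	removal man	title	FALSE
researcher	researcher	title	FALSE
retail	retail	description	FALSE
retail worker	retail worker	title	FALSE
retired	retired	title	TRUE
sailor	sailor	title	FALSE
sales representative	sales representative	title	FALSE
scientist	scientist	title	FALSE
sculptor	sculptor	title	FALSE
secretary	secretary	title	FALSE
security	security	description	FALSE
security guard	security guard	title	FALSE
self-employed	self-employed	title	TRUE
sex worker	sex worker	title	FALSE
shop assistant	shop assistant	title	FALSE
shopkeeper	shopkeeper	title	FALSE
social worker	social worker	title	FALSE
software developer	software developer	title	FALSE
soldier	soldier	title	FALSE
solicitor	solicitor	title	FALSE
staff nurse	nurse	title	FALSE
student	student	title	TRUE
support worker	support worker	title	FALSE
surveyor	surveyor	title	FALSE
tailor	tailor	title	FALSE
tattooist	tattooist	title	FALSE
taxi driver	taxi driver	title	FALSE
teacher	teacher	title	FALSE
teaching assistant	teaching assistant	title	FALSE
therapist	therapist	title	FALSE
trainee psychiatrist	psychiatrist	title	FALSE
translator	translator	title	FALSE
transport	transport	description	FALSE
unemployed	unemployed	title	TRUE
veterinary surgeon	veterinary surgeon	title	FALSE
waiter	waiter	title	FALSE
waitress	waitress	title	FALSE
warehouse operative	warehouse operative	title	FALSE
web designer	web designer	title	FALSE
window cleaner	window cleaner	title	FALSE
writer	writer	title	FALSE
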